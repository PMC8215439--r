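# Gene-expression association of the selected regions: donor/probe-averaged
# Z-scores, the 0.3 high-expression threshold, region -> top-level-structure
# counting, and the weighted presence-frequency statistic with its ranking.

.resolve_gene <- function(genes, gene) {
  if (gene %in% genes) return(gene)
  printed <- names(GENE_ALIASES)[GENE_ALIASES == gene]
  if (length(printed) && printed[1] %in% genes) return(printed[1])
  stop("unknown gene: ", gene)
}

#' Average per-donor, per-probe expression records into a Z-score table
#'
#' Collapses raw microarray-style records to one normalized Z-score per gene
#' and structure: first the mean over donors within each probe, then the
#' mean over probes. For balanced records (every probe measured in the same
#' donors) the order of averaging is immaterial; unbalanced gene/structure
#' cells are reported with a message.
#'
#' @param records Data frame with columns `gene`, `probe`, `donor`,
#'   `structure`, `z`.
#' @return Numeric matrix (genes x structures, first-appearance order) of
#'   class `expression_table`; combinations without records are `NA`.
#' @export
average_expression <- function(records) {
  need <- c("gene", "probe", "donor", "structure", "z")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  genes <- unique(records$gene)
  structures <- unique(records$structure)

  counts <- aggregate(donor ~ gene + probe + structure, records,
                      function(d) length(unique(d)))
  spread <- aggregate(donor ~ gene + structure, counts,
                      function(n) length(unique(n)))
  if (any(spread$donor > 1))
    message(sprintf("average_expression: %d gene/structure cell(s) have unbalanced donor counts across probes; averaging donors first, then probes",
                    sum(spread$donor > 1)))

  by_probe <- aggregate(z ~ gene + probe + structure, records, mean)
  by_gene <- aggregate(z ~ gene + structure, by_probe, mean)
  z <- matrix(NA_real_, length(genes), length(structures),
              dimnames = list(genes, structures))
  z[cbind(match(by_gene$gene, genes), match(by_gene$structure, structures))] <-
    by_gene$z
  structure(z, class = c("expression_table", class(z)))
}

#' Structures in which a gene is highly expressed
#'
#' Returns the top-level structures whose normalized Z-score for the gene
#' exceeds the threshold (default 0.3, the study's high-expression cut-off),
#' in table column order. Missing Z-scores never qualify.
#'
#' @param table An `expression_table` (genes x structures).
#' @param gene Gene name (printed symbol or canonical alias).
#' @param threshold High-expression threshold on the averaged Z-score.
#' @return Character vector of structure codes.
#' @export
high_expression_regions <- function(table, gene, threshold = 0.3) {
  gene <- .resolve_gene(rownames(table), gene)
  z <- table[gene, ]
  colnames(table)[!is.na(z) & z > threshold]
}

#' Count selected regions per top-level structure
#'
#' The weight of a structure is the number of selected atlas regions mapped
#' to it; a region mapped to several structures contributes to each of them.
#' Selected regions absent from the mapping are tolerated with a warning and
#' reported in the `unmapped` attribute.
#'
#' @param selected_regions Character vector of region names (duplicates are
#'   counted once).
#' @param mapping Data frame with columns `structure` and `region_name`;
#'   default the packaged mapping ([load_structure_mapping()]).
#' @param structures Structure codes defining the weight vector's order and
#'   zero-padding; default the 18 packaged codes.
#' @return Named integer vector of class `structure_weights`.
#' @export
compute_structure_weights <- function(selected_regions,
                                      mapping = load_structure_mapping(),
                                      structures = TABLE_STRUCTURES) {
  stopifnot(all(c("structure", "region_name") %in% names(mapping)))
  selected_regions <- unique(as.character(selected_regions))
  extra <- setdiff(unique(mapping$structure), structures)
  if (length(extra)) structures <- c(structures, extra)
  unmapped <- setdiff(selected_regions, mapping$region_name)
  if (length(unmapped))
    warning("selected region(s) not covered by the mapping: ",
            paste(unmapped, collapse = ", "))
  hits <- mapping[mapping$region_name %in% selected_regions, ]
  w <- table(factor(hits$structure, levels = structures))
  structure(setNames(as.integer(w), structures),
            unmapped = unmapped, class = "structure_weights")
}

#' Presence frequency of a gene in the selected regions
#'
#' The study's gene-association statistic: the dot product of the
#' per-structure selected-region counts with the gene's per-structure
#' normalized Z-scores, \eqn{\sum_s w_s Z_{gs}}. Missing Z-scores contribute
#' zero, with a warning. Higher values mean the gene is more frequently
#' highly expressed in disease-predictive territory.
#'
#' @param weights Named numeric vector of per-structure counts (see
#'   [compute_structure_weights()]).
#' @param table An `expression_table`.
#' @param gene Gene name (printed symbol or canonical alias).
#' @return Single numeric frequency score.
#' @export
presence_frequency <- function(weights, table, gene) {
  gene <- .resolve_gene(rownames(table), gene)
  miss <- setdiff(names(weights), colnames(table))
  if (length(miss))
    stop("weights refer to structure(s) absent from the table: ",
         paste(miss, collapse = ", "))
  z <- table[gene, names(weights)]
  if (anyNA(z)) {
    warning(sprintf("gene %s: %d missing Z-score(s) treated as 0", gene,
                    sum(is.na(z))))
    z[is.na(z)] <- 0
  }
  sum(as.numeric(weights) * z)
}

#' Rank all genes by presence frequency
#'
#' Computes the presence frequency of every gene in the table and sorts in
#' descending order; exact ties are broken alphabetically (and reported).
#'
#' @inheritParams presence_frequency
#' @return Data frame of class `gene_frequency_result` with columns `rank`,
#'   `gene` (as printed), `symbol` (canonical alias where one exists), and
#'   `frequency`.
#' @export
rank_genes <- function(table, weights) {
  stopifnot(nrow(table) >= 1)
  miss <- setdiff(names(weights), colnames(table))
  if (length(miss))
    stop("weights refer to structure(s) absent from the table: ",
         paste(miss, collapse = ", "))
  z <- table[, names(weights), drop = FALSE]
  n_missing <- sum(is.na(z))
  if (n_missing) {
    warning(sprintf("%d missing Z-score(s) treated as 0", n_missing))
    z[is.na(z)] <- 0
  }
  freq <- drop(z %*% as.numeric(weights))
  if (anyDuplicated(freq))
    message("rank_genes: exact frequency tie(s) broken alphabetically")
  ord <- order(-freq, rownames(table))
  genes <- rownames(table)[ord]
  symbol <- ifelse(genes %in% names(GENE_ALIASES),
                   GENE_ALIASES[genes], genes)
  structure(data.frame(rank = seq_along(genes), gene = genes,
                       symbol = unname(symbol), frequency = freq[ord],
                       row.names = NULL),
            class = c("gene_frequency_result", "data.frame"))
}

#' @export
print.gene_frequency_result <- function(x, ...) {
  cat("Gene presence-frequency ranking:\n")
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}
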