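#' Community table: counts, sample metadata, optional taxonomy
#'
#' The central container of the package: a samples-by-taxa matrix of
#' non-negative integer counts, a per-sample metadata tibble (site, depth
#' layer, grassland type), and an optional per-taxon taxonomy tibble
#' (phylum ... genus). Samples are rows; taxon ids are opaque strings.
#'
#' @param counts integer matrix, samples in rows, taxa in columns, both with
#'   unique names.
#' @param metadata data frame with a `sample_id` column matching
#'   `rownames(counts)`; typically also `site`, `layer` (one of `"T"`,
#'   `"M"`, `"S"`) and `type` (one of `"AM"`, `"TG"`, `"DG"`, `"GD"`).
#' @param taxonomy optional data frame with a `taxon_id` column plus ranks
#'   such as `phylum` and `genus`.
#' @return a `community_table` object.
#' @examples
#' cts <- matrix(rpois(12, 5), 3, 4,
#'               dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
#' community_table(cts, data.frame(sample_id = rownames(cts)))
#' @export
community_table <- function(counts, metadata, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("`counts` must have sample row names and taxon column names.")
  if (anyDuplicated(rownames(counts)))
    abort("Duplicated sample ids in counts.")
  if (anyDuplicated(colnames(counts)))
    abort("Duplicated taxon ids in counts.")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0(
      "Counts must be non-negative integers; offending cells: ",
      paste(sprintf("[%s, %s]", rownames(counts)[bad[, 1]],
                    colnames(counts)[bad[, 2]]),
            collapse = ", ")
    ))
  }
  metadata <- as_tibble(metadata)
  if (!"sample_id" %in% names(metadata))
    abort("`metadata` needs a `sample_id` column.")
  extra_meta <- setdiff(metadata$sample_id, rownames(counts))
  extra_cnt <- setdiff(rownames(counts), metadata$sample_id)
  if (length(extra_meta) || length(extra_cnt)) {
    abort(paste0(
      "Sample ids mismatch between counts and metadata. ",
      if (length(extra_meta)) paste0("In metadata only: ",
                                     paste(extra_meta, collapse = ", "), ". "),
      if (length(extra_cnt)) paste0("In counts only: ",
                                    paste(extra_cnt, collapse = ", "), ".")
    ))
  }
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ]
  if (!is.null(taxonomy)) {
    taxonomy <- as_tibble(taxonomy)
    if (!"taxon_id" %in% names(taxonomy))
      abort("`taxonomy` needs a `taxon_id` column.")
    missing_tax <- setdiff(colnames(counts), taxonomy$taxon_id)
    if (length(missing_tax))
      abort(paste0("Taxa missing from taxonomy: ",
                   paste(utils::head(missing_tax, 5), collapse = ", ")))
    taxonomy <- taxonomy[match(colnames(counts), taxonomy$taxon_id), ]
  }
  zero_taxa <- colnames(counts)[colSums(counts) == 0]
  structure(
    list(counts = counts, metadata = metadata, taxonomy = taxonomy,
         zero_taxa = zero_taxa),
    class = "community_table"
  )
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("<community_table> %d samples x %d taxa (%d all-zero)\n",
              nrow(x$counts), ncol(x$counts), length(x$zero_taxa)))
  cat("metadata: ", paste(names(x$metadata), collapse = ", "), "\n")
  if (!is.null(x$taxonomy))
    cat("taxonomy ranks: ",
        paste(setdiff(names(x$taxonomy), "taxon_id"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

n_samples <- function(ct) nrow(ct$counts)
n_taxa <- function(ct) ncol(ct$counts)

#' Drop all-zero taxa (used before diversity and null-model computations)
#' @param ct a [community_table()].
#' @return a `community_table` restricted to taxa with positive total count.
#' @export
drop_zero_taxa <- function(ct) {
  keep <- colSums(ct$counts) > 0
  community_table(ct$counts[, keep, drop = FALSE], ct$metadata,
                  if (is.null(ct$taxonomy)) NULL else
                    ct$taxonomy[keep, , drop = FALSE])
}

#' Subset a community table by sample
#' @param ct a [community_table()].
#' @param samples character vector of sample ids to keep.
#' @export
subset_samples <- function(ct, samples) {
  missing <- setdiff(samples, rownames(ct$counts))
  if (length(missing))
    abort(paste0("Unknown samples: ", paste(missing, collapse = ", ")))
  community_table(ct$counts[samples, , drop = FALSE],
                  ct$metadata[match(samples, ct$metadata$sample_id), ],
                  ct$taxonomy)
}

#' Per-sample relative abundances
#' @param ct a [community_table()].
#' @return matrix of row-normalized counts.
#' @export
relative_abundance <- function(ct) {
  tot <- rowSums(ct$counts)
  if (any(tot == 0)) abort("Samples with zero total count.")
  sweep(ct$counts, 1, tot, "/")
}

#' Read a community table from delimited files
#'
#' Counts are taxa-as-columns with sample ids in the first column; the
#' delimiter is sniffed from the extension (`.tsv` vs `.csv`).
#'
#' @param path path to the count table.
#' @param metadata_path path to the per-sample metadata table.
#' @param taxonomy_path optional per-taxon taxonomy table.
#' @return a [community_table()].
#' @export
read_community <- function(path, metadata_path, taxonomy_path = NULL) {
  read_delim_auto <- function(p) {
    sep <- if (grepl("\\.tsv$", p)) "\t" else ","
    utils::read.table(p, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  for (p in c(path, metadata_path, taxonomy_path))
    if (!is.null(p) && !file.exists(p)) abort(paste0("File not found: ", p))
  tab <- read_delim_auto(path)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- as.character(tab[[1]])
  if (!is.numeric(counts)) abort("Counts failed to parse as numbers.")
  meta <- read_delim_auto(metadata_path)
  names(meta)[1] <- "sample_id"
  meta$sample_id <- as.character(meta$sample_id)
  tax <- if (!is.null(taxonomy_path)) {
    tx <- read_delim_auto(taxonomy_path)
    names(tx)[1] <- "taxon_id"
    tx
  }
  ct <- community_table(counts, meta, tax)
  if (length(ct$zero_taxa))
    inform(sprintf("%d all-zero taxa retained (flagged in $zero_taxa).",
                   length(ct$zero_taxa)))
  ct
}

#' Write a community table to delimited files
#' @param ct a [community_table()].
#' @param counts_path,metadata_path,taxonomy_path output paths; taxonomy is
#'   written only when present and a path is given.
#' @export
write_community <- function(ct, counts_path, metadata_path,
                            taxonomy_path = NULL) {
  tab <- data.frame(sample_id = rownames(ct$counts), ct$counts,
                    check.names = FALSE)
  sep <- if (grepl("\\.tsv$", counts_path)) "\t" else ","
  utils::write.table(tab, counts_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  sep2 <- if (grepl("\\.tsv$", metadata_path)) "\t" else ","
  utils::write.table(as.data.frame(ct$metadata), metadata_path, sep = sep2,
                     row.names = FALSE, quote = FALSE)
  if (!is.null(taxonomy_path) && !is.null(ct$taxonomy)) {
    sep3 <- if (grepl("\\.tsv$", taxonomy_path)) "\t" else ","
    utils::write.table(as.data.frame(ct$taxonomy), taxonomy_path, sep = sep3,
                       row.names = FALSE, quote = FALSE)
  }
  invisible(ct)
}

#' Rarefy every sample to a fixed depth
#'
#' Subsampling is without replacement (hypergeometric marginals), one pass
#' per sample. Draws are made on taxon ids in sorted order, so permuting the
#' taxon columns and rarefying with the same seed yields the permuted result
#' of rarefying first.
#'
#' @param ct a [community_table()].
#' @param depth target reads per sample; must not exceed any sample total.
#' @param seed integer seed; required for reproducibility.
#' @return a rarefied `community_table` (taxon order preserved).
#' @export
rarefy <- function(ct, depth, seed) {
  tot <- rowSums(ct$counts)
  low <- which(tot < depth)
  if (length(low))
    abort(paste0("Rarefaction depth ", depth, " exceeds sample total for: ",
                 paste(rownames(ct$counts)[low], collapse = ", ")))
  ord <- order(colnames(ct$counts))
  cnt <- ct$counts[, ord, drop = FALSE]
  out <- matrix(0, nrow(cnt), ncol(cnt), dimnames = dimnames(cnt))
  with_seed(seed, {
    for (i in seq_len(nrow(cnt))) {
      reads <- rep.int(seq_len(ncol(cnt)), cnt[i, ])
      keep <- sample(reads, depth, replace = FALSE)
      tabulated <- tabulate(keep, nbins = ncol(cnt))
      out[i, ] <- tabulated
    }
  })
  out <- out[, colnames(ct$counts), drop = FALSE]
  community_table(out, ct$metadata, ct$taxonomy)
}
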