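# Readers/writers for the tabular and interval formats the pipeline touches.
# Conventions, fixed package-wide:
#   * beta matrices live in memory as samples x probes numeric matrices,
#     values in [0,1], NA = missing; on disk they are probes x samples TSV
#     (the array-export convention) unless the orientation flag says otherwise.
#   * probe manifest positions are 1-based bp (array-manifest convention).
#   * all BED I/O is 0-based half-open; conversion happens only at the BED
#     boundary, nowhere else.

.CANONICAL_CHROMS <- c(paste0("chr", 1:22), "chrX", "chrY")

#' Deterministic chromosome ordering
#'
#' Natural order chr1..chr22, chrX, chrY, then any other labels
#' lexicographically. This ordering defines what "consecutive probes" means
#' genome-wide, so it is fixed rather than locale-dependent.
#'
#' @param chroms character vector of chromosome labels.
#' @return character vector of levels suitable for `factor()`.
#' @export
chrom_levels <- function(chroms) {
  extra <- sort(setdiff(unique(as.character(chroms)), .CANONICAL_CHROMS))
  c(.CANONICAL_CHROMS, extra)
}

# order() helper over (chrom, pos) under the fixed chromosome order
.genome_order <- function(chrom, pos) {
  order(match(chrom, chrom_levels(chrom)), pos)
}

.check_beta_values <- function(values) {
  bad <- !is.na(values) & (values < 0 | values > 1)
  if (any(bad)) {
    stop("beta values outside [0,1]: ", sum(bad), " offending cells")
  }
  invisible(values)
}

#' Read a cohort beta-value matrix from TSV
#'
#' Expects a TSV with a header row and row labels in the first column.
#' Cells that are non-numeric or outside \[0,1\] are set to missing and
#' counted in a single warning; literal `NA` (or empty) cells are missing
#' without a warning.
#'
#' @param path TSV file path.
#' @param orientation `"probes_by_samples"` (default; rows are probes, the
#'   usual array export) or `"samples_by_probes"`. The returned matrix is
#'   always samples x probes.
#' @return numeric matrix, samples in rows, probes in columns, NA = missing.
#' @export
read_beta_matrix <- function(path,
                             orientation = c("probes_by_samples",
                                             "samples_by_probes")) {
  orientation <- match.arg(orientation)
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", check.names = FALSE,
                   colClasses = "character", na.strings = character(0))
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty beta matrix in ", path)
  row_labels <- df[[1L]]
  col_labels <- colnames(df)[-1L]
  if (anyDuplicated(row_labels)) {
    stop("duplicate row labels in ", path, ": ",
         paste(unique(row_labels[duplicated(row_labels)]), collapse = ", "))
  }
  if (anyDuplicated(col_labels)) {
    stop("duplicate column labels in ", path, ": ",
         paste(unique(col_labels[duplicated(col_labels)]), collapse = ", "))
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  declared_na <- raw == "NA" | raw == ""
  values <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  out_of_range <- !is.na(values) & (values < 0 | values > 1)
  values[out_of_range] <- NA_real_
  n_invalid <- sum((is.na(values) & !declared_na))
  if (n_invalid > 0L) {
    warning(n_invalid, " cell(s) non-numeric or outside [0,1] set to NA")
  }
  dimnames(values) <- list(row_labels, col_labels)
  if (orientation == "probes_by_samples") values <- t(values)
  values
}

#' Write a beta matrix to TSV
#'
#' @param beta samples x probes matrix as returned by [read_beta_matrix()].
#' @param path output file.
#' @param orientation on-disk layout; default probes in rows.
#' @param label header of the row-label column.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path,
                              orientation = c("probes_by_samples",
                                              "samples_by_probes"),
                              label = "probe_id") {
  orientation <- match.arg(orientation)
  .check_beta_values(beta)
  m <- if (orientation == "probes_by_samples") t(beta) else beta
  df <- data.frame(rownames(m), format(m, digits = 15, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(label, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a probe manifest
#'
#' TSV with columns `probe_id`, `chrom`, `pos` (1-based bp) and optionally
#' `island_id`. Rows are returned sorted by (chrom, pos) under the fixed
#' chromosome order, which defines probe adjacency for region calling.
#'
#' @param path TSV file path.
#' @return data.frame with class `probe_manifest`.
#' @export
read_manifest <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  probe_manifest(df)
}

#' Construct/validate a probe manifest
#'
#' @param df data.frame with `probe_id`, `chrom`, `pos`, optional `island_id`.
#' @return the manifest sorted by (chrom, pos), classed `probe_manifest`.
#' @export
probe_manifest <- function(df) {
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% colnames(df))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe ids in manifest: ",
         paste(head(unique(df$probe_id[duplicated(df$probe_id)]), 5),
               collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  if (any(is.na(df$pos)) || any(df$pos < 1L)) {
    stop("manifest positions must be integers >= 1")
  }
  df <- df[.genome_order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("probe_manifest", "data.frame")
  df
}

#' @export
write_manifest <- function(manifest, path) {
  write.table(as.data.frame(manifest), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct/validate a CpG-island set
#'
#' Intervals are 0-based half-open `[start, end)`, the BED convention.
#'
#' @param chrom,start,end,name parallel vectors (or a data.frame as `chrom`).
#' @return data.frame classed `island_set`.
#' @export
island_set <- function(chrom, start = NULL, end = NULL, name = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
  } else {
    df <- data.frame(chrom = chrom, start = start, end = end, name = name,
                     stringsAsFactors = FALSE)
  }
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (any(df$start >= df$end)) {
    stop("island intervals must satisfy start < end (0-based half-open)")
  }
  if (anyDuplicated(df$name)) stop("island names must be unique")
  df <- df[.genome_order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("island_set", "data.frame")
  df
}

# island_set (0-based half-open) <-> GRanges (1-based closed); the only
# place the coordinate conversion lives.
.islands_to_granges <- function(islands) {
  gr <- GenomicRanges::GRanges(
    islands$chrom,
    IRanges::IRanges(start = islands$start + 1L, end = islands$end))
  S4Vectors::mcols(gr)$name <- islands$name
  gr
}

.granges_to_islands <- function(gr) {
  island_set(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(S4Vectors::mcols(gr)$name)) {
      as.character(S4Vectors::mcols(gr)$name)
    } else {
      paste0("island_", seq_along(gr))
    },
    stringsAsFactors = FALSE))
}

#' Read a CpG-island BED file
#'
#' 4-column BED, 0-based half-open. A 1-based inclusive interval such as
#' chr19:41,119,032-41,120,394 is therefore stored on disk as
#' `chr19 41119031 41120394`.
#'
#' @param path BED file.
#' @return [island_set()] data.frame.
#' @export
read_islands <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  isl <- .granges_to_islands(gr)
  isl
}

#' @export
write_islands <- function(islands, path) {
  rtracklayer::export(.islands_to_granges(islands), path, format = "BED")
  invisible(path)
}

.VARIANT_CLASSES <- c("frameshift", "stop_gain", "canonical_splice",
                      "start_loss", "missense", "other")
.LOF_CLASSES <- c("frameshift", "stop_gain", "canonical_splice", "start_loss")

#' Construct/validate a variant table
#'
#' One row per variant: `gene`, `id`, `consequence_class` (one of
#' frameshift, stop_gain, canonical_splice, start_loss, missense, other),
#' `revel` (in \[0,1\], expected for missense only), `control_ac`/`control_an`
#' (population allele count / allele number) and `case_carriers`.
#'
#' @param df data.frame of variant records.
#' @return data.frame classed `variant_table`.
#' @export
variant_table <- function(df) {
  need <- c("gene", "id", "consequence_class", "revel",
            "control_ac", "control_an", "case_carriers")
  if (!all(need %in% colnames(df))) {
    stop("variant table needs columns: ", paste(need, collapse = ", "))
  }
  bad <- !(df$consequence_class %in% .VARIANT_CLASSES)
  if (any(bad)) {
    stop("unknown consequence_class in row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(df$consequence_class[bad]), collapse = ", "))
  }
  df$revel <- as.numeric(df$revel)
  df$control_ac <- as.integer(df$control_ac)
  df$control_an <- as.integer(df$control_an)
  df$case_carriers <- as.integer(df$case_carriers)
  if (any(df$control_ac < 0L) || any(df$control_an <= 0L) ||
      any(df$case_carriers < 0L)) {
    stop("allele counts must be non-negative and control_an > 0")
  }
  if (any(df$control_ac > df$control_an)) {
    stop("control_ac exceeds control_an in row(s) ",
         paste(which(df$control_ac > df$control_an), collapse = ", "))
  }
  mis <- df$consequence_class == "missense"
  if (any(mis & is.na(df$revel))) {
    warning(sum(mis & is.na(df$revel)), " missense variant(s) without REVEL")
  }
  if (any(!mis & !is.na(df$revel))) {
    warning(sum(!mis & !is.na(df$revel)),
            " non-missense variant(s) carry a REVEL score (ignored)")
  }
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Read a variant table from TSV
#' @param path TSV with the [variant_table()] columns.
#' @return `variant_table` data.frame.
#' @export
read_variants <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  variant_table(df)
}

#' @export
write_variants <- function(variants, path) {
  write.table(as.data.frame(variants), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write called epimutation regions
#'
#' Full fields go to TSV; the BED companion carries the region interval with
#' the carrier sample in the BED name field.
#'
#' @param regions region data.frame (see [call_regions()]).
#' @param tsv,bed output paths (either may be NULL to skip).
#' @return invisible list of written paths.
#' @export
write_regions <- function(regions, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    write.table(as.data.frame(regions), tsv, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  }
  if (!is.null(bed) && nrow(regions) > 0) {
    gr <- GenomicRanges::GRanges(
      regions$chrom,
      IRanges::IRanges(start = regions$start + 1L, end = regions$end))
    S4Vectors::mcols(gr)$name <- regions$sample
    rtracklayer::export(gr, bed, format = "BED")
  } else if (!is.null(bed)) {
    writeLines(character(0), bed)
  }
  invisible(list(tsv = tsv, bed = bed))
}

#' Read back a regions TSV written by [write_regions()]
#' @param path TSV file.
#' @return data.frame of regions.
#' @export
read_regions <- function(path) {
  read.table(path, header = TRUE, sep = "\t", quote = "",
             comment.char = "", stringsAsFactors = FALSE)
}
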