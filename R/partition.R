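#' Partition scheme
#'
#' Named, disjoint sets of 1-based column indices with a per-partition
#' alphabet tag: `"nucleotide"` or `"ry"` (two-state purine/pyrimidine).
#'
#' @param partitions named list of integer vectors (1-based column indices).
#' @param encoding per-partition encoding tags, recycled if length one.
#' @return an object of class `rm_scheme`.
#' @export
partition_scheme <- function(partitions, encoding = "nucleotide") {
  if (is.null(names(partitions)) || any(!nzchar(names(partitions))))
    stop("partitions must be named")
  partitions <- lapply(partitions, function(p) sort(unique(as.integer(p))))
  all_idx <- unlist(partitions, use.names = FALSE)
  if (anyDuplicated(all_idx)) stop("partitions overlap")
  encoding <- rep_len(encoding, length(partitions))
  if (!all(encoding %in% c("nucleotide", "ry")))
    stop("encoding must be 'nucleotide' or 'ry'")
  names(encoding) <- names(partitions)
  structure(list(partitions = partitions, encoding = encoding),
            class = "rm_scheme")
}

#' @export
print.rm_scheme <- function(x, ...) {
  cat("rm_scheme:\n")
  for (nm in names(x$partitions))
    cat(sprintf("  %-12s %6d columns  [%s]\n", nm, length(x$partitions[[nm]]),
                x$encoding[[nm]]))
  invisible(x)
}

scheme_labels <- function(scheme, ncols) {
  lab <- rep(NA_character_, ncols)
  for (nm in names(scheme$partitions)) lab[scheme$partitions[[nm]]] <- nm
  lab
}

scheme_from_labels <- function(labels, encoding = NULL) {
  parts <- split(seq_along(labels), labels)
  parts <- parts[order(vapply(parts, min, 1L))]
  if (is.null(encoding)) {
    encoding <- vapply(names(parts), function(nm)
      if (grepl("ry", nm, ignore.case = TRUE)) "ry" else "nucleotide", "")
  }
  partition_scheme(parts, encoding)
}

#' Build a partition scheme from per-column annotations
#'
#' Annotations assign each alignment column one functional class
#' (`codon1`, `codon2`, `codon3`, `stem`, `loop`, `other`, ...); classes
#' become partitions.  Classes may optionally be merged (e.g. stems and
#' loops into a single RNA partition, as done before clock analyses).
#'
#' @param aln an `rm_alignment`.
#' @param annotations character vector, one class per column.
#' @param merge named list, e.g. `list(rna = c("stem", "loop"))`.
#' @return an `rm_scheme`; partition sizes always sum to the column count.
#' @export
build_partition_scheme <- function(aln, annotations, merge = NULL) {
  nc <- ncol(aln$matrix)
  if (length(annotations) != nc)
    stop("annotations must label every column (", nc, " needed)")
  if (anyNA(annotations) || any(!nzchar(annotations)))
    stop("unlabeled column(s): every column needs a class")
  ann <- as.character(annotations)
  if (!is.null(merge)) {
    for (nm in names(merge)) ann[ann %in% merge[[nm]]] <- nm
  }
  scheme_from_labels(ann)
}

#' Recode a set of columns as purines/pyrimidines
#'
#' Within the selected columns, `A`, `G` and `R` become `R`; `C`, `T` and `Y`
#' become `Y`; every other symbol (other IUPAC ambiguity codes, `N`, gaps)
#' becomes missing `?`, the only information-preserving treatment for a
#' two-state recoding.  Columns outside the selection are untouched and the
#' operation is idempotent.
#'
#' @param aln an `rm_alignment`.
#' @param columns integer column indices (1-based), or the name of a
#'   partition in `scheme`.
#' @param scheme optional `rm_scheme` used to resolve a partition name; if
#'   supplied, the named partition's encoding is switched to `"ry"` in the
#'   returned `scheme` attribute.
#' @return the recoded `rm_alignment` (same dimensions).
#' @export
ry_recode <- function(aln, columns, scheme = NULL) {
  if (is.character(columns)) {
    if (is.null(scheme)) stop("a scheme is needed to resolve partition names")
    pname <- columns
    columns <- scheme$partitions[[pname]]
    if (is.null(columns)) stop("no such partition: ", pname)
    scheme$encoding[[pname]] <- "ry"
  }
  if (length(columns) && (min(columns) < 1 || max(columns) > ncol(aln$matrix)))
    stop("columns out of range")
  block <- aln$matrix[, columns, drop = FALSE]
  rec <- matrix("?", nrow(block), ncol(block))
  rec[block %in% c("A", "G", "R")] <- "R"
  rec[block %in% c("C", "T", "U", "Y")] <- "Y"
  aln$matrix[, columns] <- rec
  attr(aln, "scheme") <- scheme
  aln
}

#' Region specification
#'
#' @param name region name.
#' @param ranges two-column matrix or list of `c(start, end)` 1-based
#'   inclusive intervals; intervals must be ordered and non-overlapping.
#' @return an object of class `rm_region`.
#' @export
region_spec <- function(name, ranges) {
  if (is.list(ranges)) ranges <- do.call(rbind, ranges)
  ranges <- matrix(as.integer(ranges), ncol = 2)
  if (any(ranges[, 2] < ranges[, 1])) stop("inverted interval in region ", name)
  if (nrow(ranges) > 1) {
    if (any(ranges[-1, 1] <= ranges[-nrow(ranges), 2]))
      stop("overlapping or unordered intervals in region ", name)
  }
  structure(list(name = name, ranges = ranges), class = "rm_region")
}

#' Read region specifications from a TSV file (name, start, end)
#' @param path TSV with columns name, start, end.
#' @return list of [region_spec()] objects, one per distinct name.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  lapply(split(df, df$name)[unique(df$name)], function(d)
    region_spec(d$name[1], cbind(d$start, d$end)))
}

#' Extract and concatenate gene regions
#'
#' Region columns are concatenated in the given order; the output's column
#' labels record which region each column came from, so the extraction can be
#' analysed with one partition per genomic region.
#'
#' @param aln an `rm_alignment`.
#' @param regions list of [region_spec()] objects.
#' @return an `rm_alignment` whose width is the total width of the regions
#'   (0 columns for an empty region list).
#' @export
extract_regions <- function(aln, regions) {
  nc <- ncol(aln$matrix)
  cols <- integer(0); labs <- character(0)
  for (rg in regions) {
    idx <- unlist(apply(rg$ranges, 1, function(r) seq(r[1], r[2]),
                        simplify = FALSE))
    if (length(idx) && (min(idx) < 1 || max(idx) > nc))
      stop("region ", rg$name, " out of alignment bounds")
    cols <- c(cols, idx)
    labs <- c(labs, rep(rg$name, length(idx)))
  }
  out <- alignment(aln$matrix[, cols, drop = FALSE], taxa = aln$taxa,
                   labels = labs)
  out
}

#' Slice an alignment into consecutive non-overlapping windows
#'
#' The final window is retained even when shorter than `width`; its true
#' width is recorded so downstream consumers can filter partial windows.
#'
#' @param aln an `rm_alignment`.
#' @param width window width in columns (>= 1).
#' @return list of `rm_alignment` windows, each with attributes `start`,
#'   `end`, `width` and `partial` (logical).
#' @export
window_slice <- function(aln, width) {
  if (!is.numeric(width) || length(width) != 1 || width < 1)
    stop("width must be a positive integer")
  width <- as.integer(width)
  nc <- ncol(aln$matrix)
  starts <- seq(1L, nc, by = width)
  lapply(starts, function(s) {
    e <- min(s + width - 1L, nc)
    w <- alignment(aln$matrix[, s:e, drop = FALSE], taxa = aln$taxa,
                   labels = if (is.null(aln$labels)) NULL else aln$labels[s:e])
    attr(w, "start") <- s; attr(w, "end") <- e
    attr(w, "width") <- e - s + 1L
    attr(w, "partial") <- (e - s + 1L) < width
    w
  })
}

#' Restrict a partition scheme to a subset of columns, renumbering
#' @param scheme an `rm_scheme`.
#' @param columns columns kept (1-based, in output order).
#' @return an `rm_scheme` over the renumbered columns (empty partitions drop).
#' @export
subset_scheme <- function(scheme, columns) {
  new <- lapply(scheme$partitions, function(p) match(intersect(columns, p), columns))
  keep <- vapply(new, length, 1L) > 0
  partition_scheme(new[keep], scheme$encoding[keep])
}
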