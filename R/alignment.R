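#' Multiple sequence alignment container
#'
#' An alignment is stored as a character matrix of single upper-case symbols
#' (IUPAC nucleotide codes plus `-` for gaps and `?` for missing data), one
#' row per taxon, with an optional per-column partition label vector.
#'
#' @param matrix character matrix (taxa x columns) of single characters, or a
#'   named character vector / list of equal-length sequence strings.
#' @param taxa taxon labels; defaults to the row names of `matrix`.
#' @param labels optional per-column partition labels (length = columns).
#' @return an object of class `rm_alignment` with elements `taxa`, `matrix`
#'   and `labels`.
#' @export
alignment <- function(matrix, taxa = NULL, labels = NULL) {
  if (is.list(matrix) || (is.character(matrix) && is.null(dim(matrix)))) {
    seqs <- vapply(matrix, paste0, "", collapse = "")
    if (is.null(taxa)) taxa <- names(seqs)
    nc <- unique(nchar(seqs))
    if (length(nc) > 1) stop("ragged alignment: rows differ in length")
    matrix <- do.call(rbind, lapply(seqs, function(s)
      strsplit(toupper(s), "")[[1]]))
  } else {
    matrix <- toupper(matrix)
    if (is.null(taxa)) taxa <- rownames(matrix)
  }
  if (is.null(taxa)) stop("taxon labels are required")
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon labels: ",
                                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (length(taxa) != nrow(matrix)) stop("taxa/matrix dimension mismatch")
  alphabet <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N", "-", "?")
  bad <- setdiff(unique(as.vector(matrix)), alphabet)
  if (length(bad)) stop("characters outside the IUPAC alphabet: ",
                        paste(bad, collapse = " "))
  if (!is.null(labels) && length(labels) != ncol(matrix))
    stop("labels length must equal column count")
  dimnames(matrix) <- list(taxa, NULL)
  structure(list(taxa = taxa, matrix = matrix, labels = labels),
            class = "rm_alignment")
}

#' @export
print.rm_alignment <- function(x, ...) {
  cat(sprintf("rm_alignment: %d taxa x %d columns\n", length(x$taxa), ncol(x$matrix)))
  if (!is.null(x$labels))
    cat("partitions:", paste(sprintf("%s(%d)", names(table(x$labels)),
                                     table(x$labels)), collapse = " "), "\n")
  invisible(x)
}

#' Number of columns of an alignment
#' @param aln an `rm_alignment`.
#' @return integer column count.
#' @export
n_columns <- function(aln) ncol(aln$matrix)

# strip NEXUS [...] comments (non-nested, the dialect used here)
strip_nexus_comments <- function(txt) gsub("\\[[^]]*\\]", "", txt)

#' Read an alignment from FASTA or NEXUS
#'
#' NEXUS DATA/CHARACTERS blocks may be interleaved; `charset` statements in a
#' SETS or ASSUMPTIONS block (including stride syntax `a-b\3`) are parsed into
#' a partition scheme attached as the `labels` field and returned as the
#' `scheme` attribute.
#'
#' @param path file path.
#' @param format `"auto"` (from extension/first character), `"fasta"` or `"nexus"`.
#' @return an `rm_alignment`; for NEXUS input with charsets, the per-column
#'   labels are filled and `attr(x, "scheme")` holds the [partition_scheme()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (grepl("^#NEXUS", toupper(lines[1]))) "nexus" else "fasta"
  }
  if (format == "fasta") return(read_fasta_alignment(lines))
  read_nexus_alignment(lines)
}

read_fasta_alignment <- function(lines) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers found")
  taxa <- sub("^>\\s*", "", lines[hdr])
  taxa <- sub("\\s.*$", "", taxa)
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- mapply(function(a, b) paste0(lines[seq(a + 1, b)], collapse = ""),
                 hdr, ends)
  seqs <- gsub("\\s", "", seqs)
  if (length(unique(nchar(seqs))) > 1) stop("ragged FASTA alignment")
  alignment(stats::setNames(as.list(seqs), taxa))
}

read_nexus_alignment <- function(lines) {
  txt <- strip_nexus_comments(paste(lines, collapse = "\n"))
  low <- tolower(txt)
  # matrix body of the data/characters block
  m <- regexpr("matrix", low)
  if (m < 0) stop("NEXUS file has no MATRIX statement")
  rest <- substr(txt, m + 6, nchar(txt))
  end <- regexpr(";", rest, fixed = TRUE)
  body <- substr(rest, 1, end - 1)
  rows <- strsplit(body, "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  seqs <- list()
  for (r in rows) {
    toks <- strsplit(r, "\\s+")[[1]]
    if (length(toks) < 2) next
    nm <- gsub("^'|'$", "", toks[1])
    sq <- paste0(toks[-1], collapse = "")
    seqs[[nm]] <- paste0(if (is.null(seqs[[nm]])) "" else seqs[[nm]], sq)
  }
  if (!length(seqs)) stop("empty NEXUS matrix")
  aln <- alignment(seqs)
  # charsets
  cs <- gregexpr("charset\\s+([^=;]+)=([^;]+);", low)[[1]]
  scheme <- NULL
  if (cs[1] > 0) {
    parts <- list()
    lens <- attr(cs, "match.length")
    for (i in seq_along(cs)) {
      stmt <- substr(txt, cs[i], cs[i] + lens[i] - 1)
      nm <- trimws(sub("(?i)charset\\s+([^=;]+)=.*", "\\1", stmt, perl = TRUE))
      rng <- sub(".*=", "", stmt)
      rng <- sub(";\\s*$", "", rng)
      parts[[nm]] <- parse_charset_ranges(rng, ncol(aln$matrix))
    }
    scheme <- partition_scheme(parts)
    aln$labels <- scheme_labels(scheme, ncol(aln$matrix))
  }
  attr(aln, "scheme") <- scheme
  aln
}

# "1-12\3 14 20-30" -> sorted unique 1-based indices
parse_charset_ranges <- function(txt, ncols) {
  toks <- strsplit(trimws(txt), "\\s+")[[1]]
  idx <- integer(0)
  for (tk in toks) {
    if (grepl("\\\\", tk)) {
      p <- strsplit(tk, "\\\\")[[1]]
      stride <- as.integer(p[2])
      ab <- strsplit(p[1], "-")[[1]]
      a <- as.integer(ab[1])
      b <- if (ab[2] == ".") ncols else as.integer(ab[2])
      idx <- c(idx, seq(a, b, by = stride))
    } else if (grepl("-", tk)) {
      ab <- strsplit(tk, "-")[[1]]
      b <- if (ab[2] == ".") ncols else as.integer(ab[2])
      idx <- c(idx, seq(as.integer(ab[1]), b))
    } else {
      idx <- c(idx, as.integer(tk))
    }
  }
  sort(unique(idx))
}

#' Write an alignment to FASTA or NEXUS
#'
#' NEXUS output is non-interleaved; a partition scheme (or the alignment's
#' own column labels) is emitted as a SETS block with `charset` statements.
#'
#' @param aln an `rm_alignment`.
#' @param path output path.
#' @param format `"fasta"` or `"nexus"`.
#' @param scheme optional [partition_scheme()] to write as charsets.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("nexus", "fasta"), scheme = NULL) {
  format <- match.arg(format)
  seqs <- apply(aln$matrix, 1, paste0, collapse = "")
  if (format == "fasta") {
    out <- character(0)
    for (i in seq_along(aln$taxa))
      out <- c(out, paste0(">", aln$taxa[i]), seqs[i])
    writeLines(out, path)
    return(invisible(path))
  }
  if (is.null(scheme) && !is.null(aln$labels))
    scheme <- scheme_from_labels(aln$labels)
  nt <- length(aln$taxa); nc <- ncol(aln$matrix)
  pad <- max(nchar(aln$taxa)) + 2
  out <- c("#NEXUS", "", "BEGIN DATA;",
           sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nt, nc),
           "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
           "  MATRIX")
  for (i in seq_len(nt))
    out <- c(out, sprintf("    %-*s%s", pad, aln$taxa[i], seqs[i]))
  out <- c(out, "  ;", "END;")
  if (!is.null(scheme)) {
    out <- c(out, "", "BEGIN SETS;")
    for (nm in names(scheme$partitions))
      out <- c(out, sprintf("  charset %s = %s;", nm,
                            format_charset(scheme$partitions[[nm]])))
    out <- c(out, "END;")
  }
  writeLines(out, path)
  invisible(path)
}

# compress 1-based indices into NEXUS range syntax, detecting a single stride
format_charset <- function(idx) {
  idx <- sort(unique(idx))
  if (length(idx) > 2) {
    d <- unique(diff(idx))
    if (length(d) == 1 && d > 1)
      return(sprintf("%d-%d\\%d", idx[1], idx[length(idx)], d))
  }
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1) as.character(r) else sprintf("%d-%d", r[1], r[length(r)])
  }, ""), collapse = " ")
}
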