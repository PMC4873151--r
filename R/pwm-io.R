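#' Read position weight matrices in JASPAR PFM format
#'
#' Parses the `>ID name` / four bracketed count rows (A, C, G, T) layout and
#' converts counts to column-stochastic frequencies with a small pseudocount.
#'
#' @param path JASPAR-format file.
#' @param pseudocount added to every count before normalisation.
#' @return named list of 4 x L matrices with rownames A, C, G, T.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.5) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">"))
      stop("expected a '>' header at line ", i, call. = FALSE)
    id <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]][1]
    rows <- lapply(lines[i + 1:4], function(ln) {
      stripped <- sub("^\\s*[ACGT]", "", ln)
      as.numeric(regmatches(stripped, gregexpr("[0-9.]+", stripped))[[1]])
    })
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    m <- m + pseudocount
    out[[id]] <- sweep(m, 2, colSums(m), "/")
    i <- i + 5L
  }
  out
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections (rows are
#' positions over A, C, G, T).
#'
#' @param path MEME minimal-format file.
#' @return named list of 4 x L column-stochastic matrices (rownames A, C, G,
#'   T).
#' @export
read_meme_minimal <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\b", lines[i])) {
      id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= length(lines) &&
             !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
      if (j > length(lines))
        stop("motif ", id, " lacks a letter-probability matrix",
             call. = FALSE)
      w <- sub(".*w=\\s*([0-9]+).*", "\\1", lines[j])
      L <- as.integer(w)
      rows <- vapply(lines[j + seq_len(L)], function(ln)
        as.numeric(strsplit(trimws(ln), "\\s+")[[1]]), numeric(4))
      m <- matrix(as.numeric(rows), nrow = 4)
      dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
      out[[id]] <- m
      i <- j + L + 1L
    } else i <- i + 1L
  }
  out
}
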