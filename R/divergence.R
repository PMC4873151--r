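#' Ks distribution of a duplicate class
#'
#' Histogram plus Gaussian-kernel density (Silverman bandwidth) of the Ks
#' values of one class's representative pairs. Values above the saturation
#' cap are excluded and counted.
#'
#' @param ks numeric Ks values.
#' @param bin_width histogram bin width (default 0.05).
#' @param cap saturation guard; values >= cap are excluded (default 3).
#' @return object of class `ks_distribution`: `values`, `n_excluded`,
#'   `breaks`, `counts`, `density` (x, y) or NULL when empty.
#' @export
ks_distribution <- function(ks, bin_width = 0.05, cap = 3) {
  if (cap <= 0) stop("cap must be > 0", call. = FALSE)
  ks <- ks[!is.na(ks)]
  n_excluded <- sum(ks > cap | ks < 0)
  values <- ks[ks >= 0 & ks <= cap]
  if (length(values) == 0L) {
    if (n_excluded > 0)
      warning("all ", n_excluded, " Ks values outside [0, cap]; ",
              "empty distribution", call. = FALSE)
    return(structure(list(values = numeric(0), n_excluded = n_excluded,
                          breaks = seq(0, cap, by = bin_width),
                          counts = integer(0), density = NULL),
                     class = "ks_distribution"))
  }
  breaks <- seq(0, cap + bin_width, by = bin_width)
  counts <- as.integer(table(cut(values, breaks, right = TRUE,
                                 include.lowest = TRUE)))
  dens <- stats::density(values, bw = "nrd0", from = 0, to = cap, n = 512)
  structure(list(values = values, n_excluded = n_excluded, breaks = breaks,
                 counts = counts,
                 density = list(x = dens$x, y = dens$y, bw = dens$bw)),
            class = "ks_distribution")
}

#' Detect a secondary Ks peak
#'
#' Finds the most prominent interior local maximum of the smoothed Ks
#' density inside `search_range`. Topographic prominence of a candidate peak
#' is its height minus the higher of the two deepest valleys separating it
#' from taller terrain (curve ends count as valleys). A peak is reported only
#' if its prominence exceeds `prominence_frac` of the global density maximum.
#'
#' @param dist a [ks_distribution()].
#' @param search_range length-2 numeric (lo, hi), default `c(1.5, 2.2)`.
#' @param prominence_frac minimum prominence as a fraction of the density
#'   maximum (default 0.05).
#' @return list(location, height, prominence) or NULL when no qualifying
#'   peak exists.
#' @export
detect_secondary_peak <- function(dist, search_range = c(1.5, 2.2),
                                  prominence_frac = 0.05) {
  if (search_range[1] >= search_range[2])
    stop("search_range must satisfy lo < hi", call. = FALSE)
  d <- dist$density
  if (is.null(d)) return(NULL)
  x <- d$x; y <- d$y
  n <- length(y)
  is_max <- which(y[-c(1, n)] > y[-c(n - 1, n)] &
                  y[-c(1, n)] >= y[-c(1, 2)]) + 1L
  if (!length(is_max)) return(NULL)
  prom <- vapply(is_max, function(i) peak_prominence(y, i), numeric(1))
  in_range <- x[is_max] > search_range[1] & x[is_max] < search_range[2]
  ok <- in_range & prom >= prominence_frac * max(y)
  if (!any(ok)) return(NULL)
  best <- is_max[ok][which.max(prom[ok])]
  list(location = x[best], height = y[best],
       prominence = max(prom[ok]))
}

# topographic prominence of y[i]: height above the higher of the two deepest
# valleys separating the peak from taller terrain (curve ends act as bases)
peak_prominence <- function(y, i) {
  h <- y[i]
  n <- length(y)
  lv <- h
  if (i > 1L) {
    left <- y[seq_len(i - 1L)]
    higher <- which(left >= h)
    lv <- if (length(higher)) min(left[max(higher):(i - 1L)]) else min(left)
  }
  rv <- h
  if (i < n) {
    right <- y[(i + 1L):n]
    higher <- which(right >= h)
    rv <- if (length(higher)) min(right[seq_len(min(higher))]) else min(right)
  }
  h - max(lv, rv)
}

#' Welch t-test comparison of a divergence metric between two classes
#'
#' @param a,b numeric values (Ks, Ka or Ka/Ks) for the two groups; each needs
#'   >= 2 values with nonzero variance.
#' @return data.frame(mean_a, mean_b, t, df, p).
#' @export
compare_groups <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || stats::var(a) == 0)
    stop("group 'a' is degenerate (needs >= 2 values with nonzero variance)",
         call. = FALSE)
  if (length(b) < 2 || stats::var(b) == 0)
    stop("group 'b' is degenerate (needs >= 2 values with nonzero variance)",
         call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = FALSE)
  data.frame(mean_a = mean(a), mean_b = mean(b),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
}

#' Expression divergence of a duplicate pair
#'
#' `1 - r`, Pearson correlation of the two expression profiles; in [0, 2].
#'
#' @param a,b numeric expression vectors of equal length >= 3.
#' @return numeric, or NA (with a warning) when a profile has zero variance.
#' @export
expression_divergence <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3)
    stop("profiles must share a common length >= 3", call. = FALSE)
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero-variance expression profile; divergence undefined",
            call. = FALSE)
    return(NA_real_)
  }
  1 - stats::cor(a, b)
}

#' Regulation divergence of a duplicate pair
#'
#' Jaccard distance of the two promoter PWM hit sets:
#' `1 - |intersection| / |union|`.
#'
#' @param a,b character vectors of matched motif identifiers (set semantics).
#' @return numeric in [0, 1], or NA (with a warning) when both sets are
#'   empty.
#' @export
regulation_divergence <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both PWM hit sets empty; divergence undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - length(intersect(a, b)) / u
}

#' Promoter window around a transcription start site
#'
#' The half-open interval from `upstream` bp 5' of the TSS to `downstream`
#' bp 3' of it (800 bp total by default), strand-aware and clipped at the
#' sequence start.
#'
#' @param tss TSS coordinate (0-based).
#' @param strand `"+"` or `"-"`.
#' @param upstream,downstream window extents in bp (defaults 600 and 200).
#' @return list(start, end, clipped) with a half-open interval
#'   `[start, end)`.
#' @export
promoter_window <- function(tss, strand, upstream = 600, downstream = 200) {
  if (is.na(tss)) stop("TSS is missing", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'",
                                     call. = FALSE)
  if (strand == "+") {
    start <- tss - upstream; end <- tss + downstream
  } else {
    start <- tss - downstream; end <- tss + upstream
  }
  clipped <- start < 0
  list(start = max(start, 0), end = end, clipped = clipped)
}

#' Scan a promoter sequence with position weight matrices
#'
#' Simple log-odds scanner: a motif is reported iff its best log2-odds score
#' against a uniform background, over all offsets on both strands, reaches
#' `threshold_frac` of the motif's maximum achievable score. Offsets
#' containing N are skipped.
#'
#' @param sequence promoter DNA string over A/C/G/T/N.
#' @param pwms named list of column-stochastic 4 x L matrices with rownames
#'   A, C, G, T (e.g. from [read_jaspar_pfm()]).
#' @param threshold_frac fraction of each PWM's maximum log-odds score
#'   required for a hit (default 0.8).
#' @return character vector of matched motif names (a PWM hit set).
#' @export
scan_pwms <- function(sequence, pwms, threshold_frac = 0.8) {
  s <- strsplit(toupper(sequence), "")[[1]]
  if (!all(s %in% c("A", "C", "G", "T", "N")))
    stop("sequence alphabet must be A/C/G/T/N", call. = FALSE)
  rc <- rev(chartr("ACGT", "TGCA", s))
  hits <- character(0)
  for (nm in names(pwms)) {
    pwm <- pwms[[nm]]
    lo <- log2(pmax(pwm, 1e-9) / 0.25)
    thr <- threshold_frac * sum(apply(lo, 2, max))
    if (best_pwm_score(s, lo) >= thr || best_pwm_score(rc, lo) >= thr)
      hits <- c(hits, nm)
  }
  hits
}

best_pwm_score <- function(s, lo) {
  L <- ncol(lo); n <- length(s)
  if (n < L) return(-Inf)
  idx <- match(s, c("A", "C", "G", "T"))  # N -> NA
  best <- -Inf
  for (off in 0:(n - L)) {
    rows <- idx[off + seq_len(L)]
    if (anyNA(rows)) next
    sc <- sum(lo[cbind(rows, seq_len(L))])
    if (sc > best) best <- sc
  }
  best
}
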