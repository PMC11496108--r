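# Processing of integrated mass-isotopomer (MI) peak areas into quality-
# filtered, natural-abundance-corrected MIDs and 13C enrichment values.

#' Convert integrated MI peak areas to a MID
#'
#' @param areas Numeric vector of integrated areas for M+0..M+n (missing MI
#'   indices should be supplied as 0).
#' @param n Carbon count; defaults to `length(areas) - 1`.
#' @return MID vector of fractions, or `NULL` if all areas are zero (a
#'   missing-value marker excluded downstream).
#' @export
areas_to_mid <- function(areas, n = length(areas) - 1L) {
  stopifnot(all(areas >= 0), n >= 1)
  if (length(areas) < n + 1L) areas <- c(areas, rep(0, n + 1L - length(areas)))
  s <- sum(areas)
  if (s <= 0) return(NULL)
  areas / s
}

#' Natural-abundance binomial MID
#'
#' Expected MID of an unlabeled compound with `n` carbons given the natural
#' 13C abundance: `Bin(n, p_nat)`.
#'
#' @param n Carbon count.
#' @param p_nat Natural 13C abundance (default 0.0107).
#' @return MID vector of length `n + 1`.
#' @export
natural_mid <- function(n, p_nat = 0.0107) stats::dbinom(0:n, n, p_nat)

#' Collision filter against unlabeled control extracts
#'
#' MI peaks of a compound that are already present in unlabeled (12C) tissue
#' extracts well above the natural-abundance expectation are chromatographic
#' collisions with unrelated compounds, not isotopomers. An MI index i >= 1 is
#' removed when its apparent fraction in the unlabeled control exceeds the
#' `Bin(n, p_nat)` fraction by more than `threshold`. M+0 is always kept: an
#' unlabeled compound legitimately exceeds the binomial M+0 expectation.
#'
#' @param unlabeled_mid MID measured in the unlabeled control (mean across
#'   control replicates), or `NULL` if no control is available (all MI kept,
#'   with a warning).
#' @param n Carbon count.
#' @param threshold Maximum tolerated excess fraction (default 0.05).
#' @param p_nat Natural 13C abundance.
#' @return Logical vector of length `n + 1`: `TRUE` = keep M+i.
#' @export
collision_filter <- function(unlabeled_mid, n, threshold = 0.05,
                             p_nat = 0.0107) {
  if (is.null(unlabeled_mid)) {
    warning("no unlabeled control MID; keeping all MI indices")
    return(rep(TRUE, n + 1L))
  }
  stopifnot(length(unlabeled_mid) == n + 1L)
  excess <- unlabeled_mid - natural_mid(n, p_nat)
  keep <- excess <= threshold
  keep[1] <- TRUE
  keep
}

#' Forward natural-abundance convolution
#'
#' Maps a tracer-only MID to the MID that would be measured when each atom not
#' already 13C-labeled carries natural abundance: the binomial transform.
#'
#' @param mid Tracer-only MID (length `n + 1`).
#' @param p_nat Natural 13C abundance.
#' @return Measured-space MID.
#' @export
binomial_convolve <- function(mid, p_nat = 0.0107) {
  n <- length(mid) - 1L
  out <- numeric(n + 1L)
  for (j in 0:n) {
    if (mid[j + 1L] == 0) next
    out[(j:n) + 1L] <- out[(j:n) + 1L] +
      mid[j + 1L] * stats::dbinom(0:(n - j), n - j, p_nat)
  }
  out
}

#' Correct a measured MID for natural 13C abundance
#'
#' Inverts the lower-triangular binomial transform by back-substitution,
#' returning the tracer-only MID whose convolution with per-atom natural
#' abundance reproduces the measurement. Small negative fractions are clipped
#' to zero and the vector renormalized.
#'
#' @param measured Measured MID (length `n + 1`).
#' @param p_nat Natural 13C abundance (default 0.0107; 0 is the identity).
#' @param warn_below Negative corrected fractions below this trigger a
#'   data-quality warning (default -0.05).
#' @return Corrected MID vector.
#' @export
binomial_correct <- function(measured, p_nat = 0.0107, warn_below = -0.05) {
  n <- length(measured) - 1L
  if (p_nat == 0) return(measured)
  x <- numeric(n + 1L)
  for (j in 0:n) {
    acc <- measured[j + 1L]
    if (j > 0) {
      for (i in 0:(j - 1L)) {
        acc <- acc - x[i + 1L] * stats::dbinom(j - i, n - i, p_nat)
      }
    }
    x[j + 1L] <- acc / stats::dbinom(0, n - j, p_nat)
  }
  if (any(x < warn_below))
    warning("natural-abundance correction produced fraction < ", warn_below,
            "; data-quality flag")
  mid_clip(x)
}

#' 13C enrichment of a MID
#'
#' The average fraction of labeled carbon atoms: `e = sum(i * x_i) / n`.
#'
#' @param mid MID vector (length `n + 1`).
#' @param n Carbon count; defaults to `length(mid) - 1`.
#' @return Enrichment in `[0, 1]`.
#' @export
enrichment <- function(mid, n = length(mid) - 1L) {
  if (n < 1) stop("enrichment undefined for a carbon-free species")
  sum((0:(length(mid) - 1L)) * mid) / n
}

#' Process a long-format peak-area table into corrected MIDs
#'
#' Pipeline: per metabolite and sample, peak areas are normalized to MI
#' fractions; MI indices flagged by the collision filter (computed on the mean
#' of unlabeled-control samples) are removed for all samples of that
#' metabolite and the remaining fractions renormalized; fractions are
#' corrected for natural 13C abundance; replicate mean and sample sd are
#' computed per group in corrected space.
#'
#' @param records Data frame with columns `metabolite`, `n` (carbons),
#'   `sample`, `group`, `mi` (0-based MI index), `area`, `labeled` (logical;
#'   `FALSE` rows form the unlabeled control).
#' @param threshold Collision-filter excess threshold.
#' @param p_nat Natural 13C abundance.
#' @param correct Set `FALSE` to skip natural-abundance correction (for
#'   comparison only).
#' @return A list with `mids` (per metabolite/sample corrected MIDs), `summary`
#'   (data frame: metabolite, group, mi, mean, sd, kept) and `enrichment`
#'   (data frame: metabolite, sample, group, e).
#' @export
process_peak_areas <- function(records, threshold = 0.05, p_nat = 0.0107,
                               correct = TRUE) {
  need <- c("metabolite", "n", "sample", "group", "mi", "area", "labeled")
  stopifnot(all(need %in% names(records)))
  mids <- list(); enr <- list(); summ <- list()
  for (met in unique(records$metabolite)) {
    rm_ <- records[records$metabolite == met, ]
    n <- rm_$n[1]
    # control MID: mean over unlabeled samples
    ctl <- rm_[!rm_$labeled, ]
    ctl_mid <- NULL
    if (nrow(ctl) > 0) {
      per <- lapply(split(ctl, ctl$sample), function(d) {
        a <- numeric(n + 1L); a[d$mi + 1L] <- d$area; areas_to_mid(a, n)
      })
      per <- per[!vapply(per, is.null, logical(1))]
      if (length(per) > 0) ctl_mid <- Reduce(`+`, per) / length(per)
    }
    keep <- if (is.null(ctl_mid)) {
      warning("metabolite '", met, "': no unlabeled control; keeping all MI")
      rep(TRUE, n + 1L)
    } else collision_filter(ctl_mid, n, threshold, p_nat)

    lab <- rm_[rm_$labeled, ]
    for (smp in unique(lab$sample)) {
      d <- lab[lab$sample == smp, ]
      a <- numeric(n + 1L); a[d$mi + 1L] <- d$area
      mid <- areas_to_mid(a, n)
      if (is.null(mid)) next
      mid[!keep] <- 0
      if (sum(mid) <= 0) next
      mid <- mid / sum(mid)
      if (correct) mid <- binomial_correct(mid, p_nat)
      key <- paste(met, smp, sep = "::")
      mids[[key]] <- mid
      enr[[key]] <- data.frame(metabolite = met, sample = smp,
                               group = d$group[1], e = enrichment(mid, n),
                               stringsAsFactors = FALSE)
    }
    # replicate aggregation per group
    for (grp in unique(lab$group)) {
      smps <- unique(lab$sample[lab$group == grp])
      mats <- do.call(rbind, Filter(Negate(is.null),
                                    mids[paste(met, smps, sep = "::")]))
      if (is.null(mats) || nrow(mats) == 0) next
      mu <- colMeans(mats)
      sdv <- if (nrow(mats) > 1) apply(mats, 2, stats::sd) else rep(NA_real_,
                                                                    n + 1L)
      summ[[length(summ) + 1L]] <- data.frame(
        metabolite = met, group = grp, n = n, mi = 0:n,
        mean = mu, sd = sdv, kept = keep, stringsAsFactors = FALSE)
    }
  }
  list(mids = mids,
       summary = if (length(summ)) do.call(rbind, summ) else NULL,
       enrichment = if (length(enr)) do.call(rbind, unname(enr)) else NULL)
}
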