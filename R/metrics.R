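#' Mean trophic level of the catch (TLc)
#'
#' Catch-number-weighted mean trophic level over the species caught:
#' `TLc = sum(n_s * TL_s) / sum(n_s)`. Counts (not biomass) are the
#' weights, consistent with count-only observer records.
#'
#' @param catch_counts Named non-negative integer vector, species code to
#'   catch count.
#' @param trophic Named numeric vector, species code to trophic level; see
#'   [trophic_table()].
#' @return TLc, a unitless real bounded by the min and max trophic level of
#'   the species caught.
#' @examples
#' set_tlc(c(BET = 1, LAN = 1), c(BET = 4.81, LAN = 4.34)) # 4.575
#' @export
set_tlc <- function(catch_counts, trophic = trophic_table()) {
  catch_counts <- catch_counts[catch_counts > 0]
  if (length(catch_counts) == 0 || sum(catch_counts) < 1) {
    stop("TLc is undefined for an empty catch", call. = FALSE)
  }
  missing <- setdiff(names(catch_counts), names(trophic))
  if (length(missing)) {
    stop("no trophic level for species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tl <- trophic[names(catch_counts)]
  sum(catch_counts * tl) / sum(catch_counts)
}

#' Shannon-Wiener diversity index
#'
#' `H' = -sum(p_i * log(p_i))` over species with positive counts, with
#' `p_i = n_i / N`. Natural-log base (nats) by default; the base is
#' configurable since conventions differ.
#'
#' @param catch_counts Non-negative numeric vector of counts pooled over a
#'   stratum (names optional).
#' @param base Logarithm base (default `exp(1)`).
#' @return H', in `[0, log(S)]` for `S` species present.
#' @examples
#' shannon_index(rep(1, 10)) # log(10)
#' @export
shannon_index <- function(catch_counts, base = exp(1)) {
  if (any(catch_counts < 0)) stop("negative counts", call. = FALSE)
  n <- catch_counts[catch_counts > 0]
  if (length(n) == 0) stop("Shannon index undefined for all-zero counts",
                           call. = FALSE)
  p <- n / sum(n)
  -sum(p * log(p, base = base))
}

#' Effort-rarefied Shannon index with bootstrap interval
#'
#' Repeatedly subsamples whole sets (the resampling unit, since hooks
#' within a set are not independent) until the subsample reaches
#' approximately `target_effort` hooks, computes H' on the pooled
#' subsample, and summarizes over bootstrap replicates. This adjusts
#' diversity comparisons for unequal effort among strata.
#'
#' @param sets Data frame with a `hooks` column and wide `catch_<code>`
#'   columns.
#' @param target_effort Target total hooks per subsample; defaults to the
#'   full stratum effort (in which case every replicate uses all sets and
#'   the interval is degenerate).
#' @param n_boot Number of bootstrap replicates (>= 100 unless the target
#'   equals the full effort).
#' @param seed Integer seed.
#' @param base Logarithm base for H'.
#' @return List with `estimate` (mean bootstrap H'), `lo95`, `hi95`,
#'   `n_boot`, `target_effort`.
#' @export
rarefied_shannon <- function(sets, target_effort = sum(sets$hooks),
                             n_boot = 500, seed = 1L, base = exp(1)) {
  total <- sum(sets$hooks)
  if (target_effort > total) {
    stop("insufficient effort in stratum: ", total, " hooks < target ",
         target_effort, call. = FALSE)
  }
  catch_cols <- grep("^catch_", names(sets), value = TRUE)
  if (!length(catch_cols)) stop("no catch_<code> columns", call. = FALSE)
  cmat <- as.matrix(sets[, catch_cols, drop = FALSE])
  if (target_effort == total) {
    h <- shannon_index(colSums(cmat), base = base)
    return(list(estimate = h, lo95 = h, hi95 = h, n_boot = 0L,
                target_effort = target_effort))
  }
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  withr::local_seed(seed)
  n <- nrow(sets)
  hs <- vapply(seq_len(n_boot), function(b) {
    ord <- sample.int(n)
    keep <- ord[cumsum(sets$hooks[ord]) <= target_effort]
    if (length(keep) == 0) keep <- ord[1]
    shannon_index(colSums(cmat[keep, , drop = FALSE]), base = base)
  }, numeric(1))
  qs <- unname(quantile(hs, c(0.025, 0.975), type = 7))
  list(estimate = mean(hs), lo95 = qs[1], hi95 = qs[2], n_boot = n_boot,
       target_effort = target_effort)
}
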