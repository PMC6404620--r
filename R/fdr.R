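#' Benjamini-Hochberg FDR with a nominal hard floor
#'
#' Standard step-up Benjamini-Hochberg across `m` marker P-values (the
#' largest rank `k` with `P_(k) <= k * alpha_fdr / m` defines the rejection
#' prefix), intersected with a hard floor: rejection additionally requires
#' the nominal `P_i <= floor` (default 0.01). The floor can only remove
#' rejections, never add them. Tied P-values share the maximal qualifying
#' rank. `NA`/`NaN` P-values are excluded from `m` with a warning and carry
#' `NA` flags.
#'
#' @param pvals Numeric vector of nominal P-values in `[0, 1]`.
#' @param alpha_fdr FDR level (default 0.05).
#' @param floor Nominal hard floor for rejection (default 0.01).
#' @return A tibble (class `fdr_result`) in input order with columns `p`,
#'   `rank`, `bh_threshold` (`rank * alpha_fdr / m`), `bh_pass`,
#'   `floor_pass`, `reject`; attributes `m`, `alpha_fdr`, `floor`.
#' @export
bh_with_floor <- function(pvals, alpha_fdr = 0.05, floor = 0.01) {
  stopifnot(length(pvals) >= 1L, alpha_fdr > 0, alpha_fdr <= 1,
            floor > 0, floor <= 1)
  bad <- is.na(pvals)
  if (any(bad)) {
    warn(paste0(sum(bad), " NA/NaN p-value(s) excluded from m"))
  }
  ok <- !bad
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- sum(ok)
  p <- pvals[ok]
  rk <- rank(p, ties.method = "max")
  s <- sort(p)
  qualifies <- s <= seq_len(m) * alpha_fdr / m
  kmax <- if (any(qualifies)) max(which(qualifies)) else 0L
  bh_pass <- p <= kmax * alpha_fdr / m
  out <- tibble(
    p = pvals,
    rank = NA_integer_,
    bh_threshold = NA_real_,
    bh_pass = NA,
    floor_pass = NA,
    reject = NA
  )
  out$rank[ok] <- as.integer(rk)
  out$bh_threshold[ok] <- rk * alpha_fdr / m
  out$bh_pass[ok] <- bh_pass
  out$floor_pass[ok] <- p <= floor
  out$reject[ok] <- bh_pass & (p <= floor)
  structure(out, m = m, alpha_fdr = alpha_fdr, floor = floor,
            class = c("fdr_result", class(out)))
}
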