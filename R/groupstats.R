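#' One-sided paired t-test with Cohen's d
#'
#' @param values_A,values_B Paired per-subject values.
#' @param direction `"greater"` tests A > B, `"less"` tests A < B.
#' @return List: `t`, `df` (= n - 1), `p` (one-sided), `d`
#'   (`mean(diff)/sd(diff)`), `n`, `mean_A`, `mean_B`.
#' @export
paired_t_one_sided <- function(values_A, values_B,
                               direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(values_A) == length(values_B))
  ok <- is.finite(values_A) & is.finite(values_B)
  a <- values_A[ok]; b <- values_B[ok]
  n <- length(a)
  if (n < 3L) stop("need at least 3 paired observations")
  dif <- a - b
  s <- sd(dif)
  if (!is.finite(s) || s <= 1e-10 * max(abs(mean(dif)), .Machine$double.eps))
    stop("zero-variance paired differences")
  tt <- t.test(a, b, paired = TRUE, alternative = direction)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       d = mean(dif) / s, n = n, mean_A = mean(a), mean_B = mean(b))
}

#' Condition contrasts of connectivity with surrogate-based inclusion
#'
#' Per-edge contrasts include only subjects whose estimate was significant
#' (per the surrogate mask) in both conditions for that edge; the
#' network-mean contrast averages, per subject, the non-self edges included
#' in both conditions. Self-connections (diagonal) are always excluded.
#'
#' @param conn_A,conn_B Arrays `[subjects, M, M]` of per-subject
#'   connectivity (`[ , target, source]`).
#' @param include_A,include_B Logical arrays of the same shape (surrogate
#'   significance masks); default: all subjects included.
#' @param scope `"per-edge"`, `"network-mean"` or `"both"` (default).
#' @param direction One-sided alternative for A vs B, per contrast.
#' @param min_n Minimum included subjects for an edge (default 3); smaller
#'   edges are skipped with a notice.
#' @param holm Apply Holm correction across per-edge p-values (off by
#'   default; the per-edge tests are reported uncorrected otherwise).
#' @return Data frame: `edge` (`"i->j"` or `"network_mean"`), `from`, `to`,
#'   `n`, `df`, `t`, `p`, `d`, `mean_A`, `mean_B`.
#' @export
edge_and_mean_contrasts <- function(conn_A, conn_B, include_A = NULL,
                                    include_B = NULL,
                                    scope = c("both", "per-edge", "network-mean"),
                                    direction = c("greater", "less"),
                                    min_n = 3L, holm = FALSE) {
  scope <- match.arg(scope); direction <- match.arg(direction)
  stopifnot(length(dim(conn_A)) == 3L, all(dim(conn_A) == dim(conn_B)))
  ns <- dim(conn_A)[1L]; M <- dim(conn_A)[2L]
  include_A <- include_A %||% array(TRUE, dim(conn_A))
  include_B <- include_B %||% array(TRUE, dim(conn_B))
  both <- include_A & include_B
  rows <- list()
  if (scope %in% c("both", "per-edge")) {
    for (j in seq_len(M)) {
      for (i in seq_len(M)) {
        if (i == j) next
        keep <- which(both[, j, i])
        if (length(keep) < min_n) {
          message(sprintf("edge %d->%d: only %d included subjects; skipped",
                          i, j, length(keep)))
          next
        }
        r <- paired_t_one_sided(conn_A[keep, j, i], conn_B[keep, j, i], direction)
        rows[[length(rows) + 1L]] <-
          data.frame(edge = sprintf("%d->%d", i, j), from = i, to = j,
                     n = r$n, df = r$df, t = r$t, p = r$p, d = r$d,
                     mean_A = r$mean_A, mean_B = r$mean_B)
      }
    }
    if (holm && length(rows)) {
      ps <- vapply(rows, function(x) x$p, numeric(1))
      adj <- stats::p.adjust(ps, method = "holm")
      for (k in seq_along(rows)) rows[[k]]$p <- adj[k]
    }
  }
  if (scope %in% c("both", "network-mean")) {
    offdiag <- which(diag(M) == 0)
    subj_mean <- function(conn, msk) vapply(seq_len(ns), function(s) {
      v <- conn[s, , ][offdiag]; m <- msk[s, , ][offdiag]
      if (!any(m)) NA_real_ else mean(v[m])
    }, numeric(1))
    mA <- subj_mean(conn_A, both); mB <- subj_mean(conn_B, both)
    r <- paired_t_one_sided(mA, mB, direction)
    rows[[length(rows) + 1L]] <-
      data.frame(edge = "network_mean", from = NA_integer_, to = NA_integer_,
                 n = r$n, df = r$df, t = r$t, p = r$p, d = r$d,
                 mean_A = r$mean_A, mean_B = r$mean_B)
  }
  do.call(rbind, rows)
}

#' Pearson correlation between a connectivity summary and behavior
#'
#' @param summary Per-subject connectivity summary.
#' @param behavior Per-subject behavioral score (e.g. false-alarm rate).
#' @return List: `r`, `p` (two-sided, t transform), `n`.
#' @export
brain_behavior_correlation <- function(summary, behavior) {
  stopifnot(length(summary) == length(behavior))
  ok <- is.finite(summary) & is.finite(behavior)
  x <- summary[ok]; y <- behavior[ok]
  if (length(x) < 4L) stop("need at least 4 paired values")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
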