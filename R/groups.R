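#' Compare coefficient groups: Kruskal-Wallis with Dunn's post test
#'
#' Omnibus Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test()])
#' followed by Dunn's pairwise rank z tests with tie correction and
#' Bonferroni multiplicity adjustment.
#'
#' @param groups named list of numeric vectors, one per group (>= 2 groups,
#'   each of size >= 2).
#' @return list: `H`, `df`, `p`, `dunn` (data.frame `group1`, `group2`, `z`,
#'   `p`, `p_adj`), `degenerate` (TRUE when all values are tied across
#'   groups, in which case the tests carry no information) and `method`.
#' @export
compare_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, 1L) >= 2L))
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  gfac <- factor(rep(names(groups), vapply(groups, length, 1L)),
                 levels = names(groups))
  degenerate <- length(unique(x)) == 1L
  if (degenerate) {
    kw <- list(statistic = c(H = 0), parameter = length(groups) - 1L,
               p.value = 1)
  } else {
    kw <- stats::kruskal.test(x, gfac)
  }

  # Dunn (1964): z_ij = (Rbar_i - Rbar_j) / sqrt(S2 * (1/n_i + 1/n_j)),
  # S2 = N(N+1)/12 - sum(t^3 - t) / (12 (N - 1)) with ties t.
  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, gfac, mean)
  ns <- tapply(rk, gfac, length)
  ties <- table(x)
  S2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  cmb <- utils::combn(names(groups), 2)
  z <- p <- numeric(ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1, k]; j <- cmb[2, k]
    se <- sqrt(S2 * (1 / ns[[i]] + 1 / ns[[j]]))
    z[k] <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  dunn <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ], z = z, p = p,
                     p_adj = pmin(1, p * ncol(cmb)))
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, dunn = dunn, degenerate = degenerate,
       method = "Kruskal-Wallis (tie-corrected) + Dunn z tests, Bonferroni adjustment")
}
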