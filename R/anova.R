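# Repeated-measures ANOVA for balanced fully-crossed within-subject designs.
#
# Sums of squares come from the classical inclusion-exclusion identity over
# marginal totals: for a cell classification S, T(S) = sum over cells of
# (cell total)^2 / (cell size), and for any effect A,
# SS_A = sum over subsets S of A of (-1)^(|A|-|S|) T(S). Each within effect is
# tested against its interaction with subjects. Greenhouse-Geisser epsilon is
# estimated from the covariance of the subject-level effect contrasts;
# Mauchly's sphericity test is reported as a flag alongside.

subset_list <- function(x) {
  out <- list(character(0))
  for (el in x) out <- c(out, lapply(out, function(s) c(s, el)))
  out
}

t_term <- function(data, dv, cols) {
  if (!length(cols)) return(sum(data[[dv]])^2 / nrow(data))
  key <- do.call(paste, c(data[cols], sep = "\r"))
  sums <- rowsum(data[[dv]], key)
  sizes <- as.vector(table(key)[rownames(sums)])
  sum(sums^2 / sizes)
}

# orthonormal contrasts spanning the centered space of a k-level factor
ortho_contrasts <- function(k) {
  qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
}

#' Repeated-measures ANOVA (within-subject, balanced)
#'
#' Full-factorial decomposition of a balanced, fully-crossed within-subject
#' design: every main effect and interaction of the listed factors, each
#' tested against its interaction with subjects. For a within factor with
#' `a` levels and `n` subjects the df pair is `(a-1, (a-1)(n-1))`. Reports
#' uncorrected and Greenhouse-Geisser corrected p-values, the epsilon
#' estimate (clamped to `[1/df1, 1]`), partial eta squared
#' `SS_effect / (SS_effect + SS_error)`, and Mauchly's sphericity p as a
#' diagnostic flag (epsilon correction is always reported; Mauchly does not
#' gate it).
#'
#' @param data long-format data.frame, one row per observation.
#' @param dv name of the response column.
#' @param subject name of the subject identifier column.
#' @param factors character vector of within-subject factor columns, fully
#'   crossed and balanced; cells with replicates are averaged first.
#' @return data.frame of class `anova_table` with one row per effect:
#'   `effect`, `ss`, `df1`, `df2`, `ss_error`, `F`, `p`, `gg_epsilon`,
#'   `p_gg`, `peta2`, `mauchly_p`.
#' @export
rm_anova <- function(data, dv = "msi", subject = "subject", factors) {
  assert_that(all(c(dv, subject, factors) %in% names(data)),
              "incomplete_design", "missing columns in data")
  d <- data.frame(.y = as.numeric(data[[dv]]),
                  .s = as.character(data[[subject]]),
                  lapply(data[factors], as.character),
                  stringsAsFactors = FALSE)
  names(d) <- c(".y", ".s", factors)
  # collapse replicates within full cells
  full_key <- do.call(paste, c(d[c(".s", factors)], sep = "\r"))
  if (anyDuplicated(full_key)) {
    d <- stats::aggregate(d[".y"], by = d[c(".s", factors)], FUN = mean)
    names(d)[names(d) == ".y"] <- ".y"
  }
  levs <- lapply(d[factors], function(x) sort(unique(x)))
  nlev <- vapply(levs, length, 1L)
  subjects <- sort(unique(d$.s))
  n <- length(subjects)
  assert_that(nrow(d) == n * prod(nlev), "incomplete_design",
              "design is not balanced / fully crossed (missing cells)")

  tcache <- new.env(parent = emptyenv())
  Tof <- function(cols) {
    k <- paste0("T|", paste(sort(cols), collapse = "|"))
    if (is.null(tcache[[k]])) tcache[[k]] <- t_term(d, ".y", sort(cols))
    tcache[[k]]
  }
  ss_effect <- function(A) {
    sum(vapply(subset_list(A), function(S)
      (-1)^(length(A) - length(S)) * Tof(S), 1.0))
  }

  effects <- subset_list(factors)[-1]   # all non-empty factor subsets
  rows <- lapply(effects, function(A) {
    df1 <- prod(nlev[A] - 1)
    ss <- ss_effect(A)
    ss_err <- ss_effect(c(A, ".s"))
    df2 <- df1 * (n - 1)
    Fv <- (ss / df1) / (ss_err / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)

    # subject x cells-of-A matrix, averaged over the other factors
    cells <- interaction(d[A], sep = "\r", lex.order = TRUE)
    M <- tapply(d$.y, list(d$.s, cells), mean)
    C <- Reduce(kronecker, lapply(nlev[A], ortho_contrasts))
    B <- t(C) %*% stats::cov(M) %*% C
    dd <- nrow(B)
    if (dd == 1) {
      eps <- 1; mau_p <- NA_real_
    } else {
      eps <- sum(diag(B))^2 / (dd * sum(B^2))
      eps <- min(1, max(1 / dd, eps))
      evals <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
      if (all(evals > 1e-12)) {
        W <- prod(evals) / (mean(evals))^dd
        fchi <- -(n - 1 - (2 * dd^2 + dd + 2) / (6 * dd)) * log(W)
        mau_p <- stats::pchisq(fchi, dd * (dd + 1) / 2 - 1, lower.tail = FALSE)
      } else mau_p <- 0
    }
    data.frame(effect = paste(A, collapse = ":"), ss = ss, df1 = df1,
               df2 = df2, ss_error = ss_err, F = Fv, p = p,
               gg_epsilon = eps,
               p_gg = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
               peta2 = ss / (ss + ss_err),
               mauchly_p = mau_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ss_subject") <- ss_effect(".s")
  attr(out, "ss_total") <- sum((d$.y - mean(d$.y))^2)
  attr(out, "n_subjects") <- n
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in intersect(c("ss", "ss_error"), names(y))) y[[col]] <- signif(y[[col]], 5)
  for (col in intersect(c("F", "gg_epsilon", "peta2"), names(y))) y[[col]] <- round(y[[col]], 3)
  for (col in intersect(c("p", "p_gg", "mauchly_p"), names(y))) y[[col]] <- signif(y[[col]], 4)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
`[.anova_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("anova_table", "data.frame")
  out
}
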