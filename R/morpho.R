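#' One-way ANOVA reconstructed from group summaries
#'
#' Classic one-way fixed-effects ANOVA computed from printed group means,
#' standard errors of the mean and sample sizes alone (SD recovered as
#' se * sqrt(n)): between-group and within-group sums of squares give F
#' with (k-1, N-k) degrees of freedom. This reproduces exactly what
#' \code{aov} on the raw data would report, without needing the raw
#' measurements.
#'
#' @param groups data.frame with columns \code{label}, \code{mean},
#'   \code{se}, \code{n} (n >= 2 per group, >= 2 groups).
#' @return list with \code{F}, \code{p}, \code{df} (length 2),
#'   \code{ss_between}, \code{ss_within}.
#' @export
anova_oneway_summary <- function(groups) {
  groups <- as.data.frame(groups)
  stopifnot(all(c("mean", "se", "n") %in% names(groups)),
            nrow(groups) >= 2)
  if (any(groups$n < 2)) stop("every group needs n >= 2")
  if (any(groups$se <= 0)) stop("standard errors must be positive")
  k <- nrow(groups)
  n <- groups$n
  m <- groups$mean
  sd <- groups$se * sqrt(n)
  N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * sd^2)
  df1 <- k - 1
  df2 <- N - k
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), ss_between = ssb, ss_within = ssw)
}

#' Welch two-sample t-test from group summaries
#'
#' @param m1,se1,n1 mean, SEM and size of group 1.
#' @param m2,se2,n2 mean, SEM and size of group 2.
#' @return list with \code{t}, \code{df} (Welch-Satterthwaite), \code{p}
#'   (two-sided).
#' @export
welch_t_summary <- function(m1, se1, n1, m2, se2, n2) {
  v1 <- se1^2   # = s1^2 / n1
  v2 <- se2^2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Compact significance letters from pairwise Welch tests
#'
#' All pairwise Welch t-tests from summaries; two groups share a letter
#' iff their pairwise p-value is >= \code{alpha} (no multiplicity
#' correction). Groups are ordered by descending mean and letters are the
#' maximal runs of mutually non-significant neighbours, so identical
#' groups share \code{"a"} and fully separated groups get distinct
#' letters.
#'
#' @param groups data.frame with columns \code{label}, \code{mean},
#'   \code{se}, \code{n}.
#' @param alpha significance level (default 0.01).
#' @return data.frame: \code{label}, \code{mean}, \code{letters}, sorted by
#'   descending mean; attribute \code{"pvalues"} holds the pairwise p-value
#'   matrix.
#' @export
pairwise_letters <- function(groups, alpha = 0.01) {
  groups <- as.data.frame(groups)
  stopifnot(all(c("label", "mean", "se", "n") %in% names(groups)))
  groups <- groups[order(-groups$mean), , drop = FALSE]
  k <- nrow(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(groups$label, groups$label))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      w <- welch_t_summary(groups$mean[i], groups$se[i], groups$n[i],
                           groups$mean[j], groups$se[j], groups$n[j])
      p[i, j] <- w$p
    }
  }
  ns <- p >= alpha
  diag(ns) <- TRUE
  # maximal runs over the mean-ordered groups in which all pairs are n.s.
  runs <- list()
  i <- 1
  while (i <= k) {
    j <- i
    while (j < k && all(ns[i:(j + 1), i:(j + 1)])) j <- j + 1
    runs[[length(runs) + 1]] <- i:j
    i <- if (j == k) k + 1 else i + 1
  }
  # drop runs fully contained in another
  keep <- vapply(seq_along(runs), function(a) {
    !any(vapply(seq_along(runs), function(b)
      a != b && all(runs[[a]] %in% runs[[b]]), logical(1)))
  }, logical(1))
  runs <- runs[keep]
  letter <- vapply(seq_len(k), function(g)
    paste(letters[which(vapply(runs, function(r) g %in% r, logical(1)))],
          collapse = ""), character(1))
  out <- data.frame(label = groups$label, mean = groups$mean,
                    letters = letter, stringsAsFactors = FALSE)
  attr(out, "pvalues") <- p
  out
}

#' Read a morphometric summary table
#'
#' TSV with header columns \code{indicator}, \code{group}, \code{mean},
#' \code{se}, \code{n}; one row per indicator x group. A bundled table of
#' published worker-bee body-size summaries (three *Apis cerana*
#' populations, 10 indicators, means in micrometres +/- SEM) ships at
#' \code{system.file("extdata", "acerana_morphometry.tsv",
#' package = "sweepscan")}.
#'
#' @param path TSV file path.
#' @param pm_is_sd interpret the +/- column as SD instead of SEM; it is
#'   converted to SEM via sqrt(n).
#' @return data.frame with the five columns above.
#' @export
read_morpho_table <- function(path, pm_is_sd = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("indicator", "group", "mean", "se", "n")
  if (!all(need %in% names(tab))) {
    stop("morphometry table must have columns: ", paste(need, collapse = ", "))
  }
  if (pm_is_sd) tab$se <- tab$se / sqrt(tab$n)
  tab
}

#' ANOVA + significance letters for every indicator of a morphometry table
#'
#' @param tab data.frame from \code{\link{read_morpho_table}}.
#' @param alpha level for letter sharing (default 0.01).
#' @return data.frame with one row per indicator x group: \code{indicator},
#'   \code{group}, \code{mean}, \code{se}, \code{n}, \code{letters},
#'   \code{anova_F}, \code{anova_p}.
#' @export
morpho_report <- function(tab, alpha = 0.01) {
  out <- lapply(split(tab, tab$indicator), function(d) {
    g <- data.frame(label = d$group, mean = d$mean, se = d$se, n = d$n)
    a <- anova_oneway_summary(g)
    let <- pairwise_letters(g, alpha = alpha)
    d <- d[match(let$label, d$group), , drop = FALSE]
    d$letters <- let$letters
    d$anova_F <- a$F
    d$anova_p <- a$p
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
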