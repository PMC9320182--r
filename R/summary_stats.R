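# Descriptive statistics with CV classes, correlation matrices with
# significance, and hierarchical clustering of metals.

#' Descriptive statistics with CV classification
#'
#' Mean, sample SD (n-1 denominator), and coefficient of variation
#' (`sd/mean x 100`) with its low/intermediate/high class, for each numeric
#' variable, optionally within groups.
#'
#' @param samples Data frame.
#' @param variables Columns to describe; defaults to the physicochemical and
#'   concentration columns of a campaign.
#' @param by Optional grouping column name.
#' @return Data frame: `group` (if any), `variable`, `n`, `mean`, `sd`, `cv`,
#'   `cv_label` (`"n/a"` when the mean is not positive).
#' @export
describe <- function(samples, variables = NULL, by = NULL) {
  if (is.null(variables)) {
    variables <- intersect(
      c("temperature_C", "pH", "EC_uScm", "TDS_ppm", paste0(hm_metals(), "_mgL")),
      names(samples))
  }
  one <- function(d, g) {
    rows <- lapply(variables, function(v) {
      x <- d[[v]]
      n <- length(x)
      m <- mean(x)
      s <- if (n < 2L) {
        warning("single observation for '", v, "': sd reported as 0")
        0
      } else stats::sd(x)
      cv <- if (m > 0) s / m * 100 else NA_real_
      lab <- if (is.na(cv)) "n/a" else classify("CV", cv)
      data.frame(variable = v, n = n, mean = m, sd = s, cv = cv,
                 cv_label = lab, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!is.null(g)) out <- cbind(data.frame(group = g, stringsAsFactors = FALSE), out)
    out
  }
  if (is.null(by)) return(one(samples, NULL))
  groups <- split(samples, samples[[by]])
  out <- do.call(rbind, lapply(names(groups), function(g) one(groups[[g]], g)))
  row.names(out) <- NULL
  out
}

#' Correlation matrix with two-sided p-values
#'
#' Pairwise-complete correlations (Pearson default, Spearman optional) with
#' p-values from the t transform `t = r sqrt(n-2) / sqrt(1-r^2)`. The matrix
#' is symmetric with unit diagonal; cells involving a zero-variance variable
#' are `NA` and flagged.
#'
#' @param samples Data frame.
#' @param variables Columns to correlate (defaults as in [describe()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with matrices `r`, `p`, `n`, the `method`, and
#'   `zero_variance` (character vector of flagged variables).
#' @export
correlation_matrix <- function(samples, variables = NULL,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(variables)) {
    variables <- intersect(
      c("temperature_C", "pH", "EC_uScm", "TDS_ppm", paste0(hm_metals(), "_mgL")),
      names(samples))
  }
  x <- as.matrix(samples[, variables])
  k <- ncol(x)
  zv <- variables[apply(x, 2, function(col) stats::sd(col, na.rm = TRUE) == 0)]
  r <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  p <- r
  nmat <- matrix(0L, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- stats::complete.cases(x[, i], x[, j])
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (n < 3L || variables[i] %in% zv || variables[j] %in% zv) next
      rij <- stats::cor(x[ok, i], x[ok, j], method = method)
      r[i, j] <- r[j, i] <- rij
      if (abs(rij) >= 1) {
        p[i, j] <- p[j, i] <- 0
      } else {
        tstat <- rij * sqrt(n - 2) / sqrt(1 - rij^2)
        p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), df = n - 2)
      }
    }
  }
  list(r = r, p = p, n = nmat, method = method, zero_variance = zv)
}

#' Long-format correlation table with significance stars
#'
#' @param cm Result of [correlation_matrix()].
#' @return Data frame `var1, var2, r, p, stars` (upper triangle only);
#'   `*` for p < 0.05, `**` for p < 0.01 (two-sided, no multiplicity
#'   correction).
#' @export
correlation_long <- function(cm) {
  v <- rownames(cm$r)
  rows <- list()
  for (i in seq_along(v)) {
    for (j in seq_along(v)) {
      if (j <= i) next
      p <- cm$p[i, j]
      rows[[paste(i, j)]] <- data.frame(
        var1 = v[i], var2 = v[j], r = cm$r[i, j], p = p,
        stars = if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Hierarchical clustering of metals
#'
#' Standardises each variable to z-scores, computes Euclidean distances
#' between variable profiles (variables as objects, samples as features),
#' and clusters with Ward's criterion (`hclust` method `"ward.D2"`; average
#' linkage optional). Zero-variance variables are excluded with a warning.
#' Deterministic given input order; `hclust` breaks distance ties by lowest
#' index.
#'
#' @param samples Data frame.
#' @param variables Columns to cluster (>= 2 after exclusions); defaults to
#'   the metal concentration columns.
#' @param linkage `"ward"` (default) or `"average"`.
#' @return List with `tree` (an `hclust`), `merges` (data frame
#'   `node1, node2, height`; negative entries are leaves), and `labels`.
#' @export
cluster_metals <- function(samples, variables = NULL,
                           linkage = c("ward", "average")) {
  linkage <- match.arg(linkage)
  if (is.null(variables)) variables <- paste0(hm_metals(), "_mgL")
  x <- as.matrix(samples[, variables])
  keep <- apply(x, 2, stats::sd) > 0
  if (!all(keep)) {
    warning("excluding zero-variance variable(s): ",
            paste(variables[!keep], collapse = ", "))
  }
  x <- x[, keep, drop = FALSE]
  if (ncol(x) < 2L) stop("need at least 2 variables with spread", call. = FALSE)
  z <- scale(x)
  d <- stats::dist(t(z), method = "euclidean")
  tree <- stats::hclust(d, method = if (linkage == "ward") "ward.D2" else "average")
  merges <- data.frame(node1 = tree$merge[, 1], node2 = tree$merge[, 2],
                       height = tree$height)
  list(tree = tree, merges = merges, labels = tree$labels)
}

#' Export a linkage tree as a plain-text merge list
#'
#' @param clustering Result of [cluster_metals()].
#' @param path Output CSV path (`node1, node2, height`, with a `# labels:`
#'   header comment).
#' @return `path`, invisibly.
#' @export
write_linkage <- function(clustering, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# labels: ", paste(clustering$labels, collapse = ",")), con)
  utils::write.csv(clustering$merges, con, row.names = FALSE)
  invisible(path)
}
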