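#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test: zero differences are discarded (the
#' classical convention; `zero_method = "pratt"` keeps them in the ranking
#' instead), ties receive midranks, and for up to `exact_limit` non-zero
#' pairs the p-value is computed by full enumeration of all sign
#' assignments of the null distribution; beyond that a normal approximation
#' with continuity and tie corrections is used.
#'
#' @param x,y Paired score vectors of equal length.
#' @param exact_limit Largest n for exact enumeration (default 15).
#' @param zero_method `"wilcox"` (discard zeros) or `"pratt"`.
#' @return A list with `statistic` (V, the sum of ranks of positive
#'   differences), `p_value` (two-sided), `n_used`, and `method`.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))$p_value  # 0.0625
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 15L,
                                 zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  if (!length(x)) stop_invalid("empty input")
  d <- as.numeric(x) - as.numeric(y)
  if (!all(is.finite(d))) stop_invalid("scores must be finite")
  if (zero_method == "wilcox") d <- d[d != 0]
  if (!length(d) || all(d == 0)) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  if (zero_method == "pratt") {
    keep <- d != 0
    r <- r[keep]; d <- d[keep]
  }
  n <- length(d)
  v <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= exact_limit) {
    # enumerate all 2^n sign assignments of the (midrank) null distribution
    signs <- matrix(FALSE, 2^n, n)
    for (j in seq_len(n))
      signs[, j] <- rep(c(FALSE, TRUE), each = 2^(j - 1L),
                        length.out = 2^n)
    w_all <- as.vector(signs %*% r)
    p <- mean(abs(w_all - mu) >= abs(v - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n_used = n, method = method)
}

#' Cohen's kappa for interobserver agreement
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` over the shared category set,
#' with the expected agreement `p_e` from the product of the observers'
#' marginal distributions.
#'
#' @param r1,r2 Paired categorical rating vectors of equal length.
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohens_kappa(rep(1:2, c(25, 25)),
#'              rep(c(1, 2, 1, 2), c(20, 5, 10, 15)))  # 0.4
#' @export
cohens_kappa <- function(r1, r2) {
  if (length(r1) != length(r2)) stop_invalid("ratings must have equal length")
  if (!length(r1)) stop_invalid("empty ratings")
  cats <- sort(unique(c(r1, r2)))
  t1 <- factor(r1, levels = cats)
  t2 <- factor(r2, levels = cats)
  tab <- table(t1, t2)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) {
    warning("both observers constant and identical; kappa defined as 1",
            call. = FALSE)
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Subject rating table
#'
#' Long-format table of subject experience scores: one row per subject,
#' condition (`"quiet"` / `"conventional"`), repeat (1 or 2) and item, with
#' scores on a 0-10 scale.
#'
#' @param subject,condition,repeat_idx,item,score Equal-length vectors.
#' @return A `data.frame` of class `rating_table`.
#' @export
rating_table <- function(subject, condition, repeat_idx, item, score) {
  score <- as.numeric(score)
  if (any(!is.finite(score)) || any(score < 0 | score > 10))
    stop_invalid("scores must lie in [0, 10]")
  df <- data.frame(subject = as.character(subject),
                   condition = as.character(condition),
                   repeat_idx = as.integer(repeat_idx),
                   item = as.character(item),
                   score = score, stringsAsFactors = FALSE)
  class(df) <- c("rating_table", "data.frame")
  df
}

#' @rdname rating_table
#' @param path CSV file with columns `subject, condition, repeat, item,
#'   score` (or `repeat_idx`).
#' @export
read_rating_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("repeat." %in% names(df)) names(df)[names(df) == "repeat."] <- "repeat_idx"
  if ("repeat" %in% names(df)) names(df)[names(df) == "repeat"] <- "repeat_idx"
  need <- c("subject", "condition", "repeat_idx", "item", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_invalid("rating table missing column(s): ",
                                 paste(miss, collapse = ", "))
  rating_table(df$subject, df$condition, df$repeat_idx, df$item, df$score)
}

#' Synthetic rating table with given per-item condition means and SDs
#'
#' Draws subject scores from normal distributions (rounded to the 0-10
#' scale) so summaries of the generated table reproduce the requested
#' means within sampling error; used to exercise the rating statistics on
#' realistic tables.
#'
#' @param means Named list: `means[[item]][[condition]]` giving the target
#'   mean.
#' @param sds Same structure, target standard deviations.
#' @param n_subjects Number of subjects.
#' @param repeat_sd SD of the within-subject difference between the two
#'   repeats.
#' @param seed Integer seed.
#' @return A [rating_table()].
#' @export
make_rating_table <- function(means, sds, n_subjects = 5L, repeat_sd = 0.9,
                              seed = 1L) {
  rows <- with_seed(seed, {
    out <- list()
    for (item in names(means)) {
      for (cond in names(means[[item]])) {
        base <- stats::rnorm(n_subjects, means[[item]][[cond]],
                             sds[[item]][[cond]])
        for (rep_i in 1:2) {
          sc <- base + stats::rnorm(n_subjects, 0, repeat_sd / sqrt(2))
          sc <- pmin(10, pmax(0, round(sc * 2) / 2))
          out[[length(out) + 1L]] <- data.frame(
            subject = sprintf("S%02d", seq_len(n_subjects)),
            condition = cond, repeat_idx = rep_i, item = item, score = sc,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })
  rating_table(rows$subject, rows$condition, rows$repeat_idx, rows$item,
               rows$score)
}

#' Summarise repeated ratings
#'
#' Per item and condition: the mean absolute difference between the first
#' and second presentation (and its SD), and the mean +/- SD of the
#' per-subject averaged scores. Incomplete subject/condition/item pairs are
#' listed in an exclusion report rather than silently dropped.
#'
#' @param table A [rating_table()].
#' @return A list with `repeat_differences` (data.frame: item, condition,
#'   mean_abs_diff, sd_abs_diff), `condition_means` (data.frame: item,
#'   condition, mean, sd over per-subject averages), and `excluded`.
#' @export
summarize_repeats <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  key <- interaction(table$subject, table$condition, table$item, drop = TRUE)
  excluded <- character(0)
  diffs <- list(); avgs <- list()
  for (k in levels(key)) {
    rows <- table[key == k, ]
    s1 <- rows$score[rows$repeat_idx == 1L]
    s2 <- rows$score[rows$repeat_idx == 2L]
    if (length(s1) != 1L || length(s2) != 1L) {
      excluded <- c(excluded, k)
      next
    }
    diffs[[k]] <- data.frame(item = rows$item[1L],
                             condition = rows$condition[1L],
                             d = abs(s1 - s2))
    avgs[[k]] <- data.frame(item = rows$item[1L],
                            condition = rows$condition[1L],
                            avg = (s1 + s2) / 2)
  }
  agg <- function(df, col) {
    sp <- split(df[[col]], list(df$item, df$condition), drop = TRUE)
    out <- do.call(rbind, lapply(names(sp), function(nm) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
      data.frame(item = parts[1L], condition = parts[2L],
                 mean = mean(sp[[nm]]),
                 sd = if (length(sp[[nm]]) > 1L) stats::sd(sp[[nm]]) else 0)
    }))
    rownames(out) <- NULL
    out
  }
  d_all <- do.call(rbind, diffs)
  a_all <- do.call(rbind, avgs)
  rd <- agg(d_all, "d"); names(rd)[3:4] <- c("mean_abs_diff", "sd_abs_diff")
  list(repeat_differences = rd,
       condition_means = agg(a_all, "avg"),
       excluded = excluded)
}

#' Paired condition comparison of rating items
#'
#' Runs the exact Wilcoxon signed-rank test per item on the per-subject
#' averaged scores of the two conditions.
#'
#' @param table A [rating_table()].
#' @param conditions Character pair to compare (x vs y).
#' @return Data frame with item, per-condition means/SDs, V and p.
#' @export
compare_conditions <- function(table,
                               conditions = c("quiet", "conventional")) {
  stopifnot(inherits(table, "rating_table"))
  sm <- summarize_repeats(table)
  items <- unique(table$item)
  out <- lapply(items, function(it) {
    sub <- table[table$item == it, ]
    avg <- stats::aggregate(score ~ subject + condition, data = sub,
                            FUN = mean)
    a <- avg$score[avg$condition == conditions[1L]][
      order(avg$subject[avg$condition == conditions[1L]])]
    b <- avg$score[avg$condition == conditions[2L]][
      order(avg$subject[avg$condition == conditions[2L]])]
    wt <- wilcoxon_signed_rank(a, b)
    data.frame(item = it,
               mean_1 = mean(a), sd_1 = stats::sd(a),
               mean_2 = mean(b), sd_2 = stats::sd(b),
               statistic = wt$statistic, p_value = wt$p_value)
  })
  res <- do.call(rbind, out)
  names(res)[2:5] <- c(paste0("mean_", conditions[1L]),
                       paste0("sd_", conditions[1L]),
                       paste0("mean_", conditions[2L]),
                       paste0("sd_", conditions[2L]))
  res
}
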