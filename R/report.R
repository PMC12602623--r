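#' Bradley robustness bands and power thresholds
#'
#' At nominal level `alpha`, Bradley's stringent criterion accepts empirical
#' rejection rates in \[0.9a, 1.1a\] and the liberal criterion \[0.5a, 1.5a\]
#' (at a = .05: \[.045, .055\] and \[.025, .075\]). Coverage bands mirror
#' them: stringent \[.945, .955\], liberal \[.925, .975\]. Power >= .80
#' counts as adequate and >= .90 as strong. All band edges are inclusive.
#'
#' @param alpha Nominal significance level. Default 0.05.
#' @return A list of class `criterion_bands`.
#' @export
criterion_bands <- function(alpha = 0.05) {
  # band edges rounded to 12 digits so that printed edges such as .045
  # compare as inclusive despite binary floating point (0.9 * 0.05 > 0.045)
  structure(list(alpha = alpha,
                 stringent_t1 = round(c(0.9, 1.1) * alpha, 12),
                 liberal_t1 = round(c(0.5, 1.5) * alpha, 12),
                 stringent_cov = round(1 - rev(c(0.9, 1.1) * alpha), 12),
                 liberal_cov = round(1 - rev(c(0.5, 1.5) * alpha), 12),
                 power_good = 0.80, power_strong = 0.90),
            class = "criterion_bands")
}

#' Classify an empirical type-I error rate
#'
#' @param rate Rejection rate in \[0, 1\] (vectorized).
#' @param bands A `criterion_bands` object.
#' @return Character vector: `"stringent"`, `"liberal"`,
#'   `"overly_conservative"` or `"overly_liberal"`.
#' @export
classify_type1 <- function(rate, bands = criterion_bands()) {
  stopifnot(all(rate >= 0 & rate <= 1))
  ifelse(rate >= bands$stringent_t1[1] & rate <= bands$stringent_t1[2],
         "stringent",
  ifelse(rate >= bands$liberal_t1[1] & rate <= bands$liberal_t1[2],
         "liberal",
  ifelse(rate < bands$liberal_t1[1], "overly_conservative",
         "overly_liberal")))
}

#' Classify an empirical coverage rate
#'
#' @param rate Coverage rate in \[0, 1\] (vectorized).
#' @param bands A `criterion_bands` object.
#' @return Character vector: `"stringent"`, `"liberal"`, `"too_narrow"`
#'   (coverage below the liberal band: intervals too narrow) or
#'   `"too_broad"`.
#' @export
classify_coverage <- function(rate, bands = criterion_bands()) {
  stopifnot(all(rate >= 0 & rate <= 1))
  ifelse(rate >= bands$stringent_cov[1] & rate <= bands$stringent_cov[2],
         "stringent",
  ifelse(rate >= bands$liberal_cov[1] & rate <= bands$liberal_cov[2],
         "liberal",
  ifelse(rate < bands$liberal_cov[1], "too_narrow", "too_broad")))
}

#' Classify an empirical power estimate
#'
#' @param rate Rejection rate under a true effect (vectorized).
#' @param bands A `criterion_bands` object.
#' @return Character vector: `"strong"` (>= .90), `"adequate"` (>= .80) or
#'   `"underpowered"`.
#' @export
classify_power <- function(rate, bands = criterion_bands()) {
  stopifnot(all(rate >= 0 & rate <= 1))
  ifelse(rate >= bands$power_strong, "strong",
         ifelse(rate >= bands$power_good, "adequate", "underpowered"))
}

rank_of <- function(class) {
  # common ordering across the type-I and coverage scales; larger is better
  unname(c(stringent = 3L, liberal = 2L,
           overly_conservative = 1L, overly_liberal = 1L,
           too_narrow = 1L, too_broad = 1L,
           strong = 3L, adequate = 2L, underpowered = 1L)[class])
}

collapse_summaries <- function(summaries, bands, which = c("t1cov", "power")) {
  which <- match.arg(which)
  s <- summaries
  s$het_source <- ifelse(s$model_id <= 2, "predictor_of_interest",
                         "other_predictor")
  s$variance <- ifelse(s$g == 0, "homoskedastic", "heteroskedastic")
  s$normality <- ifelse(s$dist == "normal", "normal", "non-normal")
  if (which == "t1cov") {
    null_model <- s$model_id %in% c(1, 3)
    s$class <- ifelse(null_model,
                      classify_type1(s$rejection_rate, bands),
                      NA)
    has_cov <- !null_model & !is.na(s$coverage_rate)
    s$class[has_cov] <- classify_coverage(s$coverage_rate[has_cov], bands)
    s <- s[!is.na(s$class), ]
  } else {
    s <- s[s$model_id %in% c(2, 4), ]
    s$class <- classify_power(s$rejection_rate, bands)
  }
  if (nrow(s) == 0) {
    return(data.frame(het_source = character(), variance = character(),
                      normality = character(), n = integer(),
                      method = character(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  s$rank <- rank_of(s$class)
  # worst class a method attains across the sub-scenarios collapsed into a
  # cell (g levels within homo/het, distributions within normal/non-normal,
  # and the model pair sharing a heteroskedasticity source)
  agg <- stats::aggregate(
    rank ~ het_source + variance + normality + n + method,
    data = s, FUN = min)
  agg
}

tier_label <- function(rank, which) {
  if (which == "t1cov") {
    c("fail", "liberal", "stringent")[rank]
  } else {
    c("underpowered", "adequate", "strong")[rank]
  }
}

#' Guidance matrices: which methods hold up where
#'
#' Collapses grid summaries into the two practitioner-facing matrices: one
#' for type-I error / coverage, one for power. Cells are keyed by
#' heteroskedasticity source (the model pair), homoskedastic vs
#' heteroskedastic (g = 0 vs g > 0), normal vs non-normal errors, and sample
#' size. A method is listed at the *worst* class it attains across the
#' sub-scenarios collapsed into a cell, so membership in a tier means the
#' method held that tier throughout the cell. Cells where every method
#' reaches the same top tier are abbreviated `"all methods"`; in cells where
#' no method reaches the acceptable tier, the best-performing method(s) are
#' reported in parentheses.
#'
#' @param summaries Grid summary data frame from [run_grid()].
#' @param bands A `criterion_bands` object.
#' @return List of class `guidance_tables` with data frames
#'   `type1_coverage` and `power`; each row is one cell with the tier
#'   membership strings.
#' @export
guidance_tables <- function(summaries, bands = criterion_bands()) {
  need <- unique(summaries$method)
  build <- function(which) {
    agg <- collapse_summaries(summaries, bands, which)
    if (nrow(agg) == 0) {
      return(data.frame(het_source = character(), variance = character(),
                        normality = character(), n = integer(),
                        stringsAsFactors = FALSE))
    }
    cells <- unique(agg[, c("het_source", "variance", "normality", "n")])
    cells <- cells[order(cells$het_source, cells$n, cells$variance,
                         cells$normality), ]
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      cell <- merge(cells[i, ], agg)
      top <- cell$method[cell$rank == 3L]
      mid <- cell$method[cell$rank == 2L]
      best_note <- ""
      if (length(top) + length(mid) == 0 && nrow(cell) > 0) {
        # no method acceptable: name the best attained (diagnostic rescan)
        best_note <- paste(cell$method, collapse = ", ")
      }
      data.frame(cells[i, , drop = FALSE],
                 top_tier = if (length(top) == length(need) &&
                                length(need) > 1) "all methods"
                            else paste(sort(top), collapse = ", "),
                 mid_tier = paste(sort(mid), collapse = ", "),
                 best_if_none = best_note,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    names(out)[names(out) == "top_tier"] <-
      if (which == "t1cov") "stringent" else "power_90"
    names(out)[names(out) == "mid_tier"] <-
      if (which == "t1cov") "liberal" else "power_80"
    rownames(out) <- NULL
    out
  }
  structure(list(type1_coverage = build("t1cov"), power = build("power")),
            class = "guidance_tables")
}

#' @export
print.guidance_tables <- function(x, ...) {
  cat("Type I error / coverage guidance (worst class across the cell):\n")
  print(x$type1_coverage, right = FALSE)
  cat("\nPower guidance:\n")
  print(x$power, right = FALSE)
  invisible(x)
}
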