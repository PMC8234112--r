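#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples.  The statistic reported is
#' \eqn{U = \min(U_1, U_2)} with \eqn{U_1 = n_1 n_2 + n_1(n_1+1)/2 - R_1},
#' where \eqn{R_1} is the rank sum of the first sample (mid-ranks under
#' ties).  The two-sided p-value is exact (full enumeration of the
#' \eqn{\binom{n_1+n_2}{n_1}} allocations) when both samples have at most 8
#' observations and there are no ties; otherwise a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param sample1,sample2 numeric vectors; both must be nonempty.
#' @return an object of class \code{rfid_test} with fields \code{statistic},
#'   \code{p_value}, \code{n1}, \code{n2}, \code{method}.
#' @export
mann_whitney_u <- function(sample1, sample2) {
  if (length(sample1) == 0L || length(sample2) == 0L)
    stop("both samples must be nonempty", call. = FALSE)
  n1 <- length(sample1); n2 <- length(sample2)
  r <- rank(c(sample1, sample2))
  R1 <- sum(r[seq_len(n1)])
  U1 <- n1 * n2 + n1 * (n1 + 1) / 2 - R1
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  ties <- anyDuplicated(c(sample1, sample2)) > 0L

  if (n1 <= 8L && n2 <= 8L && !ties) {
    combos <- utils::combn(n1 + n2, n1)
    null_U1 <- n1 * n2 + n1 * (n1 + 1) / 2 - colSums(matrix(
      r[combos], nrow = n1))
    p <- min(1, 2 * mean(null_U1 <= U))
    method <- "Mann-Whitney U (exact)"
  } else {
    N <- n1 + n2
    tie_tab <- table(c(sample1, sample2))
    sigma2 <- (n1 * n2 / 12) *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - n1 * n2 / 2 + 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z))
    }
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  structure(list(statistic = U, p_value = p, n1 = n1, n2 = n2,
                 method = method),
            class = "rfid_test")
}

#' Chi-square goodness-of-fit test
#'
#' \eqn{\chi^2 = \sum (O_i - E_i)^2 / E_i} over \eqn{k \ge 2} bins with
#' \eqn{df = k - 1} and an upper-tail p-value.
#'
#' @param observed_counts,expected_counts equal-length numeric vectors; every
#'   expected count must be positive.
#' @return an \code{rfid_test} with fields \code{statistic}, \code{p_value},
#'   \code{df}, \code{method}.
#' @export
chi_square_gof <- function(observed_counts, expected_counts) {
  if (length(observed_counts) != length(expected_counts))
    stop("observed and expected must have equal length", call. = FALSE)
  if (length(observed_counts) < 2L)
    stop("at least 2 bins required", call. = FALSE)
  if (any(expected_counts <= 0))
    stop("expected counts must all be positive", call. = FALSE)
  stat <- sum((observed_counts - expected_counts)^2 / expected_counts)
  df <- length(observed_counts) - 1L
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 df = df, method = "Chi-square goodness of fit"),
            class = "rfid_test")
}

#' Pearson correlation of daily flight activity with weather
#'
#' Inner-joins the daily activity series with the weather table on date and
#' reports the Pearson correlation (with two-sided t-test p-value) of the
#' daily flight count against mean temperature and against precipitation,
#' plus the temperature-precipitation correlation.  A constant series makes
#' the correlation undefined; it is then reported as NA with an explanatory
#' method tag.
#'
#' @param daily data.frame from \code{\link{daily_series}}.
#' @param weather data.frame with columns \code{date}, \code{mean_temp},
#'   \code{precipitation}.
#' @return list of three \code{rfid_test} objects: \code{r_temp},
#'   \code{r_precip}, \code{r_temp_precip}.
#' @export
weather_correlation <- function(daily, weather) {
  merged <- merge(daily, weather, by = "date")
  if (nrow(merged) < 3L)
    stop("fewer than 3 paired days after joining on date", call. = FALSE)
  pearson <- function(x, y, label) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(structure(list(statistic = NA_real_, p_value = NA_real_,
                            n = length(x),
                            method = paste0("Pearson r (", label,
                                            "): undefined, constant series")),
                       class = "rfid_test"))
    ct <- stats::cor.test(x, y, method = "pearson")
    structure(list(statistic = unname(ct$estimate),
                   p_value = ct$p.value, n = length(x),
                   method = paste0("Pearson r (", label, ")")),
              class = "rfid_test")
  }
  list(r_temp = pearson(merged$n_flights, merged$mean_temp,
                        "flights vs temperature"),
       r_precip = pearson(merged$n_flights, merged$precipitation,
                          "flights vs precipitation"),
       r_temp_precip = pearson(merged$mean_temp, merged$precipitation,
                               "temperature vs precipitation"))
}

#' @export
print.rfid_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic), " p =", format(x$p_value), "\n")
  if (!is.null(x$df)) cat("  df =", x$df, "\n")
  if (!is.null(x$n1)) cat("  n1 =", x$n1, " n2 =", x$n2, "\n")
  invisible(x)
}
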