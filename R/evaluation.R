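#' Fit statistics between predicted and observed bloom dates
#'
#' Computes the standard agreement statistics for phenology-model
#' evaluation from paired predicted and observed day-of-year values.
#' With errors `e = pred - obs`:
#'
#' * `rmse = sqrt(mean(e^2))`
#' * `mae = mean(abs(e))`
#' * `bias = mean(e)` -- positive means the model predicts *later* than
#'   observed
#' * `r2` -- the squared Pearson correlation of predictions and
#'   observations; reported as `NA` when either series is constant (or
#'   `n < 2`), where the correlation is undefined
#'
#' These satisfy `rmse >= mae >= |bias|` and
#' `rmse^2 = bias^2 + var_pop(e)` (population variance).
#'
#' @param pred,obs numeric vectors of equal length (`n >= 1`), paired by
#'   season; typically day-of-year values.
#' @return a one-row tibble with columns `rmse`, `mae`, `bias`, `r2`,
#'   `n`.
#' @examples
#' evaluate_fit(pred = c(92, 94, 103), obs = c(90, 95, 100))
#' @export
evaluate_fit <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("pred and obs must have equal length (", length(pred), " vs ",
         length(obs), ")", call. = FALSE)
  }
  if (length(pred) == 0L) {
    stop("empty input: need at least one prediction-observation pair",
         call. = FALSE)
  }
  pred <- as.numeric(pred)
  obs <- as.numeric(obs)
  if (anyNA(pred) || anyNA(obs)) {
    stop("missing values in pred or obs", call. = FALSE)
  }
  e <- pred - obs
  n <- length(e)
  r2 <- if (n >= 2 && sd(pred) > 0 && sd(obs) > 0) {
    cor(pred, obs)^2
  } else {
    NA_real_
  }
  tibble(rmse = sqrt(mean(e^2)), mae = mean(abs(e)), bias = mean(e),
         r2 = r2, n = n)
}
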