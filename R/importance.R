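# Gain-based variable importance and grouped contributions.

#' Gain importance of a fitted classifier
#'
#' Sums each variable's split gains across every tree in the ensemble and
#' standardizes them. The default standardization is shares summing to 1
#' (percent contributions comparable additively across variables); a
#' max-normalized variant (top variable = 1) is available behind the
#' `normalize` flag. Variables never used in a split get 0.
#'
#' @param model a `suitability_model` or `gbt` object with at least one
#'   tree.
#' @param normalize `"share"` (sum to 1, default) or `"max"` (top = 1).
#' @return data.frame with `variable`, `gain` (raw summed gain) and
#'   `share`, in descending share order.
#' @export
gain_importance <- function(model, normalize = c("share", "max")) {
  normalize <- match.arg(normalize)
  booster <- if (inherits(model, "suitability_model")) model$booster else model
  if (!inherits(booster, "gbt") || length(booster$trees) == 0)
    stop("untrained classifier")
  g <- booster$gain
  tot <- if (normalize == "share") sum(g) else max(g)
  share <- if (tot > 0) g / tot else g * 0
  out <- data.frame(variable = names(g), gain = as.numeric(g),
                    share = as.numeric(share))
  out <- out[order(-out$share, out$variable), ]
  rownames(out) <- NULL
  out
}

#' Default predictor grouping
#'
#' Rainfall-based, temperature-based and soil variable groups. The
#' rainfall group includes the rainfall coefficient of variation by
#' default (it is rainfall-derived); set `cv_in_rainfall = FALSE` for the
#' strict three-variable rainfall-sum grouping. Both readings are
#' legitimate for "combined rainfall influence" totals, so reports should
#' state which was used.
#'
#' @param cv_in_rainfall include `rain_cv` in the rainfall group
#'   (default `TRUE`).
#' @return named list of character vectors partitioning the eight
#'   variables.
#' @export
variable_groups <- function(cv_in_rainfall = TRUE) {
  rain <- c("rain_growing_season", "rain_mar_sep", "rain_sowing_month")
  if (cv_in_rainfall) {
    rain <- c(rain, "rain_cv")
    other <- character(0)
  } else {
    other <- "rain_cv"
  }
  g <- list(
    rainfall = rain,
    temperature = c("dtr_mar_sep", "tmean_growing_season", "tmean_mar_sep"),
    soil = "soil_organic_carbon"
  )
  if (length(other) > 0) g$rainfall_variability <- other
  g
}

#' Grouped importance contributions
#'
#' Sums per-variable shares within each group; the grouping must cover
#' every variable of the importance table exactly once.
#'
#' @param importance data.frame from [gain_importance()].
#' @param grouping named list of character vectors, see
#'   [variable_groups()].
#' @return data.frame with `group` and `share`.
#' @export
group_contributions <- function(importance, grouping = variable_groups()) {
  members <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(members))
    stop("grouping assigns a variable more than once")
  miss <- setdiff(importance$variable, members)
  if (length(miss) > 0)
    stop(sprintf("variable(s) missing from grouping: %s",
                 paste(miss, collapse = ", ")))
  share <- vapply(grouping, function(vs) {
    sum(importance$share[importance$variable %in% vs])
  }, numeric(1))
  data.frame(group = names(grouping), share = as.numeric(share),
             row.names = NULL)
}
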