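#' Centred contrast coding for analysis factors
#'
#' Builds the centred dummy codings used throughout the battery's models:
#' each factor level (other than the baseline) becomes a 0/1 dummy from which
#' the observed mean is subtracted, so that every derived column has mean zero
#' over the rows it is built from. With centred codes, the model intercept is
#' the grand mean and lower-order effects are evaluated as averages over the
#' levels of the other predictors rather than at a reference level. For a
#' balanced 3-level condition factor with baseline `LV`, the `HV` dummy codes
#' `{LV: -1/3, HV: 2/3, HVB: -1/3}`. A pooled mode codes `LV` against the
#' union of the other levels as a single centred column (balanced groups:
#' `{LV: -2/3, HV: 1/3, HVB: 1/3}`), as used for the Bayes-factor models.
#'
#' Centring constants are computed from observed frequencies, so the columns
#' are exactly mean-zero even after trial exclusions unbalance the cells.
#'
#' @param data A data frame of trial records.
#' @param specs Named list describing the derived columns. Each element is a
#'   list with fields:
#'   \describe{
#'     \item{`type`}{`"factor"` (default) or `"numeric"`.}
#'     \item{`baseline`}{for factors, the baseline level (dummies are built
#'       for every other observed level).}
#'     \item{`pooled`}{for factors, optional character vector of levels pooled
#'       into a single dummy against the baseline.}
#'     \item{`levels`}{optional explicit level set; rows with labels outside
#'       it are an error.}
#'     \item{`scale`}{for numeric predictors, a divisor applied before
#'       centring (default 1).}
#'   }
#'   The name of each element is the source column in `data`.
#' @param prefix Separator between the source column and the level in derived
#'   column names (default `"_"`).
#' @return A list of class `"contrast_scheme"` with `data` (the augmented
#'   table), and `scheme`, a tibble with one row per (column, level) pair
#'   giving the numeric code assigned to each level.
#' @examples
#' d <- data.frame(condition = rep(c("LV", "HV", "HVB"), each = 4))
#' cs <- build_contrasts(d, list(condition = list(baseline = "LV")))
#' unique(cs$data$condition_HV)   # 2/3 for HV, -1/3 otherwise
#' @export
build_contrasts <- function(data, specs, prefix = "_") {
  stopifnot(is.data.frame(data), is.list(specs), length(names(specs)) == length(specs))
  scheme <- list()
  for (col in names(specs)) {
    sp <- specs[[col]]
    if (!col %in% names(data)) stop("column `", col, "` not found in data")
    type <- sp$type %||% "factor"
    if (type == "numeric") {
      scale <- sp$scale %||% 1
      v <- data[[col]] / scale
      newcol <- paste0(col, prefix, "c")
      data[[newcol]] <- v - mean(v, na.rm = TRUE)
      scheme[[length(scheme) + 1L]] <- tibble::tibble(
        factor = col, column = newcol, level = NA_character_,
        code = NA_real_, centring = mean(v, na.rm = TRUE), scale = scale)
      next
    }
    v <- as.character(data[[col]])
    obs <- unique(v[!is.na(v)])
    lev <- sp$levels %||% obs
    if (length(bad <- setdiff(obs, lev))) {
      stop("unknown level(s) in `", col, "`: ", paste(bad, collapse = ", "))
    }
    baseline <- sp$baseline %||% lev[1]
    if (!baseline %in% lev) stop("baseline `", baseline, "` is not a level of `", col, "`")
    if (!is.null(sp$pooled)) {
      pooled <- sp$pooled
      if (length(bad <- setdiff(pooled, lev))) {
        stop("unknown pooled level(s) in `", col, "`: ", paste(bad, collapse = ", "))
      }
      dummy <- as.numeric(v %in% pooled)
      newcol <- paste0(col, prefix, "pooled")
      ctr <- mean(dummy)
      data[[newcol]] <- dummy - ctr
      codes <- ifelse(lev %in% pooled, 1 - ctr, -ctr)
      scheme[[length(scheme) + 1L]] <- tibble::tibble(
        factor = col, column = newcol, level = lev, code = codes,
        centring = ctr, scale = 1)
    } else {
      for (l in setdiff(lev, baseline)) {
        dummy <- as.numeric(v == l)
        newcol <- paste0(col, prefix, l)
        ctr <- mean(dummy)
        data[[newcol]] <- dummy - ctr
        codes <- ifelse(lev == l, 1 - ctr, -ctr)
        scheme[[length(scheme) + 1L]] <- tibble::tibble(
          factor = col, column = newcol, level = lev, code = codes,
          centring = ctr, scale = 1)
      }
    }
  }
  structure(list(data = tibble::as_tibble(data),
                 scheme = dplyr::bind_rows(scheme)),
            class = "contrast_scheme")
}

#' @export
print.contrast_scheme <- function(x, ...) {
  cat("Centred contrast scheme (", nrow(x$scheme), " codes over ",
      length(unique(x$scheme$factor)), " predictors)\n", sep = "")
  print(x$scheme, n = Inf)
  invisible(x)
}
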