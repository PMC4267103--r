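#' Demographic inputs: annual live births
#'
#' A demography is either an explicit year-by-year table of live births or a
#' base-year birth count plus a constant annual growth rate `r`, in which case
#' `births_t = base_births * (1 + r)^(t - base_year)`. Deaths in a projection
#' scale proportionally with the birth series, so a growing population yields
#' rising deaths even under constant coverage.
#'
#' @param base_year Integer calendar year anchoring the projection.
#' @param births Optional tibble/data frame with columns `year` and `births`
#'   (strictly positive). Takes precedence over `base_births`.
#' @param base_births Live births at `base_year`; used with `growth_rate` when
#'   `births` is not given.
#' @param growth_rate Constant annual growth rate (e.g. `0.02` for 2%/year).
#'
#' @return An object of class `lst_demography`.
#' @examples
#' demography(2008, base_births = 100000, growth_rate = 0.02)
#' @export
demography <- function(base_year, births = NULL, base_births = NULL,
                       growth_rate = 0) {
  base_year <- as.integer(base_year)
  if (is.null(births)) {
    if (is.null(base_births)) {
      abort("supply either `births` or `base_births`")
    }
    stopifnot(base_births > 0, growth_rate > -1)
    out <- list(base_year = base_year, births = NULL,
                base_births = as.numeric(base_births),
                growth_rate = as.numeric(growth_rate))
  } else {
    births <- as_tibble(births)
    stopifnot(all(c("year", "births") %in% names(births)))
    if (any(births$births <= 0)) abort("births must be strictly positive")
    if (anyDuplicated(births$year)) abort("duplicate year in births table")
    out <- list(base_year = base_year,
                births = arrange(births, .data$year),
                base_births = NULL, growth_rate = NULL)
  }
  structure(out, class = "lst_demography")
}

#' Live births for a set of years
#'
#' @param dem An [demography()] object.
#' @param years Integer vector of calendar years.
#' @return Numeric vector of live births, one per year.
#' @export
births_for <- function(dem, years) {
  stopifnot(inherits(dem, "lst_demography"))
  years <- as.integer(years)
  if (is.null(dem$births)) {
    return(dem$base_births * (1 + dem$growth_rate)^(years - dem$base_year))
  }
  idx <- match(years, dem$births$year)
  if (anyNA(idx)) {
    abort(paste0("no birth count for year(s): ",
                 paste(years[is.na(idx)], collapse = ", ")))
  }
  dem$births$births[idx]
}

#' @export
print.lst_demography <- function(x, ...) {
  if (is.null(x$births)) {
    cat(sprintf("<demography> base year %d, %s births, growth %.2f%%/yr\n",
                x$base_year, format(x$base_births, big.mark = ","),
                100 * x$growth_rate))
  } else {
    cat(sprintf("<demography> base year %d, explicit births for %d year(s)\n",
                x$base_year, nrow(x$births)))
  }
  invisible(x)
}
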