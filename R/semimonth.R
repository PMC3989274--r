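#' Assign calving-season semimonthly periods
#'
#' Each survey season (December through March) is divided into eight
#' semimonthly periods: the 1st--15th of a month is half "A" and the
#' 16th through month end is half "B", giving December A (ordinal 1)
#' through March B (ordinal 8). December dates belong to the season
#' labelled "year/year+1".
#'
#' @param date a `Date` vector (or string coercible with `as.Date`);
#'   every date must fall in December--March.
#' @return A data frame with one row per date: `season_start_year`
#'   (integer calendar year of the season's December), `season` label
#'   ("2009/2010"), `month` abbreviation, `half` ("A"/"B") and
#'   `semimonth` ordinal 1--8.
#' @examples
#' assign_semimonth(as.Date("2009-12-15"))  # December A, season 2009/2010
#' assign_semimonth(as.Date("2010-03-16"))  # March B
#' @export
assign_semimonth <- function(date) {
  date <- as.Date(date)
  if (anyNA(date)) stop("unparseable date")
  lt <- as.POSIXlt(date)
  mon <- lt$mon + 1L          # 1..12
  day <- lt$mday
  year <- lt$year + 1900L
  ok <- mon %in% c(12L, 1L, 2L, 3L)
  if (!all(ok))
    stop("dates outside the December-March calving season: ",
         paste(format(date[!ok]), collapse = ", "))
  season_start <- ifelse(mon == 12L, year, year - 1L)
  half <- ifelse(day <= 15L, "A", "B")
  mon_ord <- match(mon, c(12L, 1L, 2L, 3L))   # Dec=1 .. Mar=4
  semimonth <- (mon_ord - 1L) * 2L + ifelse(half == "A", 1L, 2L)
  data.frame(
    season_start_year = as.integer(season_start),
    season = paste0(season_start, "/", season_start + 1L),
    month = c("Dec", "Jan", "Feb", "Mar")[mon_ord],
    half = half,
    semimonth = as.integer(semimonth),
    stringsAsFactors = FALSE
  )
}

#' Enumerate the eight semimonths of a season
#'
#' @param season_start_year calendar year of the season's December.
#' @return Data frame of 8 rows: semimonth ordinal, month, half, and the
#'   first/last date of each period.
#' @export
semimonth_periods <- function(season_start_year) {
  y <- as.integer(season_start_year)
  months <- c(12L, 1L, 2L, 3L)
  years <- c(y, y + 1L, y + 1L, y + 1L)
  out <- do.call(rbind, lapply(1:4, function(i) {
    m <- months[i]; yr <- years[i]
    last <- as.integer(format(seq(as.Date(sprintf("%d-%02d-01", yr, m)),
                                  by = "month", length.out = 2)[2] - 1, "%d"))
    data.frame(
      semimonth = c((i - 1L) * 2L + 1L, (i - 1L) * 2L + 2L),
      month = c("Dec", "Jan", "Feb", "Mar")[i],
      half = c("A", "B"),
      start = as.Date(sprintf("%d-%02d-%02d", yr, m, c(1L, 16L))),
      end = as.Date(sprintf("%d-%02d-%02d", yr, m, c(15L, last)))
    )
  }))
  out$season <- paste0(y, "/", y + 1L)
  out
}

# day-of-season (1 = Dec 1) for a date within the season starting year y
day_of_season <- function(date, season_start_year) {
  as.integer(as.Date(date) -
               as.Date(sprintf("%d-12-01", season_start_year))) + 1L
}
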