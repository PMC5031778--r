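#' Read and write the pipeline's CSV formats
#'
#' Daily temperature files have columns `date` (ISO-8601), `tmin_c`,
#' `tmax_c`, one row per day; trap-capture files have columns
#' `check_date,site,orchard_type,lure,trap_id,males,females`. Both readers
#' validate the invariants the pipeline relies on (unique dates,
#' `tmin <= tmax`, non-negative counts).
#'
#' @param path File path.
#' @return A validated tibble.
#' @name pcm_io
NULL

#' @rdname pcm_io
#' @export
read_temperatures <- function(path) {
  temps <- readr::read_csv(
    path,
    col_types = readr::cols(
      date = readr::col_date(),
      tmin_c = readr::col_double(),
      tmax_c = readr::col_double()
    )
  )
  out <- as_temperature_table(temps)
  daily_degree_days(out$tmin_c, out$tmax_c)  # validates tmin <= tmax
  out
}

#' @rdname pcm_io
#' @export
read_trap_records <- function(path) {
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      check_date = readr::col_date(),
      site = readr::col_character(),
      orchard_type = readr::col_character(),
      lure = readr::col_character(),
      trap_id = readr::col_character(),
      males = readr::col_double(),
      females = readr::col_double()
    )
  )
  as_trap_table(records)
}

#' @rdname pcm_io
#' @param x Table to write.
#' @export
write_temperatures <- function(x, path) {
  readr::write_csv(as_temperature_table(x), path)
  invisible(path)
}

#' @rdname pcm_io
#' @export
write_trap_records <- function(x, path) {
  readr::write_csv(as_trap_table(x), path)
  invisible(path)
}
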