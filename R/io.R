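# Bottle-CSV schema and file I/O.

.bottle_mandatory <- c("cruise", "station", "date_iso", "lat_degn",
                       "lon_dege", "sst_c", "sss", "ta_umol_kg",
                       "dic_umol_kg")
.bottle_optional <- c("do_percent", "no3_umol_kg", "po4_umol_kg",
                      "sio4_umol_kg", "label")
.bottle_numeric <- c("lat_degn", "lon_dege", "sst_c", "sss", "ta_umol_kg",
                     "dic_umol_kg", "do_percent", "no3_umol_kg",
                     "po4_umol_kg", "sio4_umol_kg")

#' Read a bottle-sample CSV
#'
#' Reads the fixed bottle schema (`cruise, station, date_iso, lat_degn,
#' lon_dege, sst_c, sss, ta_umol_kg, dic_umol_kg` plus optional
#' `do_percent, no3_umol_kg, po4_umol_kg, sio4_umol_kg, label`), coerces
#' the numeric columns, reports non-numeric cells row by row, and logs the
#' count of rows with missing TA or DIC (kept in the table, excluded from
#' speciation by downstream analyses).
#'
#' @param path CSV file path.
#' @return data.frame of class `"transect"`.
#' @export
read_bottle_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(.bottle_mandatory, names(raw))
  if (length(miss))
    stop("bottle CSV missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  for (cl in intersect(.bottle_numeric, names(raw))) {
    v <- raw[[cl]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(num))
    if (length(bad))
      stop("non-numeric value(s) in column '", cl, "' at row(s) ",
           paste(bad, collapse = ", "))
    raw[[cl]] <- num
  }
  raw$station <- suppressWarnings(as.integer(raw$station))
  n_bad <- sum(is.na(raw$ta_umol_kg) | is.na(raw$dic_umol_kg))
  if (n_bad > 0)
    message(n_bad, " row(s) with missing TA or DIC (flagged; ",
            "excluded from speciation)")
  structure(raw, class = c("transect", "data.frame"))
}

#' Write a transect to a bottle CSV
#'
#' Numeric columns are written with 6 significant digits so repeated runs
#' with the same configuration and seed are byte-identical.
#'
#' @param transect a `"transect"` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bottle_csv <- function(transect, path) {
  write_csv6(transect, path)
}

# write any data.frame with numeric columns at 6 significant digits
write_csv6 <- function(df, path) {
  out <- as.data.frame(df)
  for (cl in names(out))
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]]))
      out[[cl]] <- signif(out[[cl]], 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
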