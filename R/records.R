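#' Position-quantity record store
#'
#' The terminal output of the system: one row per completed inspection,
#' keyed by the 8-digit position uid, with the fused egg count and a
#' "MM-DD HH:MM:SS" display timestamp (a full ISO-8601 timestamp is kept
#' internally). The store is append-only — re-inspecting a nest adds a new
#' row — with strictly increasing, gap-free ids, and round-trips losslessly
#' through CSV (the uid column stays text so leading zeros survive).
#'
#' @return An object of class `"record_store"`.
#' @export
record_store <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- data.frame(Id = integer(0), Uid = character(0),
                         Number = integer(0), Time = character(0),
                         TimeISO = character(0), stringsAsFactors = FALSE)
  structure(env, class = "record_store")
}

#' @export
print.record_store <- function(x, ...) {
  cat(sprintf("<record store: %d row(s)>\n", nrow(x$rows)))
  if (nrow(x$rows) > 0) print(utils::head(x$rows[, 1:4], 10))
  invisible(x)
}

#' Append an inspection record
#'
#' @param store a [record_store()].
#' @param uid 8-digit position string; validated via [parse_position()].
#' @param number fused egg count, >= 0 (zero counts are recorded too).
#' @param time POSIXct timestamp or a preformatted "MM-DD HH:MM:SS" string.
#' @return the appended record as a one-row data.frame (Id, Uid, Number,
#'   Time), invisibly also stored.
#' @export
add_record <- function(store, uid, number, time = Sys.time()) {
  stopifnot(inherits(store, "record_store"))
  parse_position(uid)  # raises format/range errors for invalid uids
  number <- as.integer(number)
  if (is.na(number) || number < 0) {
    stop("number must be a non-negative integer", call. = FALSE)
  }
  if (inherits(time, "POSIXt")) {
    display <- format(time, "%m-%d %H:%M:%S")
    iso <- format(time, "%Y-%m-%dT%H:%M:%S")
  } else {
    display <- as.character(time)
    iso <- NA_character_
  }
  id <- nrow(store$rows) + 1L
  row <- data.frame(Id = id, Uid = uid, Number = number,
                    Time = display, TimeISO = iso, stringsAsFactors = FALSE)
  store$rows <- rbind(store$rows, row)
  row[, c("Id", "Uid", "Number", "Time")]
}

#' Query records for one position
#'
#' @param store a [record_store()].
#' @param uid valid 8-digit position string.
#' @return data.frame of matching rows (Id, Uid, Number, Time) in id order.
#' @export
query_by_uid <- function(store, uid) {
  stopifnot(inherits(store, "record_store"))
  parse_position(uid)
  rows <- store$rows[store$rows$Uid == uid, c("Id", "Uid", "Number", "Time")]
  rows[order(rows$Id), ]
}

#' Export and import the record table as CSV
#'
#' Header `Id,Uid,Number,Time`; the Uid column is written (and read back)
#' as text so zero-padding is preserved.
#'
#' @param store a [record_store()].
#' @param path CSV file path.
#' @return `export_records_csv()` returns the number of data rows written;
#'   `import_records_csv()` returns a fresh [record_store()].
#' @export
export_records_csv <- function(store, path) {
  stopifnot(inherits(store, "record_store"))
  df <- store$rows[, c("Id", "Uid", "Number", "Time")]
  utils::write.csv(df, path, row.names = FALSE)
  nrow(df)
}

#' @rdname export_records_csv
#' @export
import_records_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(Id = "integer", Uid = "character",
                                             Number = "integer", Time = "character"))
  store <- record_store()
  for (i in seq_len(nrow(df))) {
    add_record(store, df$Uid[i], df$Number[i], df$Time[i])
  }
  store
}
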