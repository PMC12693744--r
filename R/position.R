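#' 8-digit cage position code
#'
#' Every nest site is named by an 8-digit identifier: two zero-padded
#' digits each for the pigeon house (1-25), the cage within the building
#' (1-4), the cage group (1-99) and the nest within the cage (1-6), in that
#' order. The identifier is the "key" of every position-quantity record and
#' is what the cage barcode carries.
#'
#' @param house house number, 1-25.
#' @param cage cage number within the building, 1-4.
#' @param group cage group number, 1-99.
#' @param nest nest number within the cage, 1-6.
#' @return An object of class `"position_code"`.
#' @examples
#' format_position(position_code(1, 1, 21, 4))  # "01012104"
#' @export
position_code <- function(house, cage, group, nest) {
  fields <- list(house = house, cage = cage, group = group, nest = nest)
  ranges <- list(house = c(1, 25), cage = c(1, 4),
                 group = c(1, 99), nest = c(1, 6))
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (length(v) != 1 || is.na(v) || v != as.integer(v)) {
      stop(sprintf("field '%s' must be a single integer", nm), call. = FALSE)
    }
    rg <- ranges[[nm]]
    if (v < rg[1] || v > rg[2]) {
      stop(sprintf("field '%s' out of range: %d not in [%d, %d]",
                   nm, as.integer(v), rg[1], rg[2]), call. = FALSE)
    }
    fields[[nm]] <- as.integer(v)
  }
  structure(fields, class = "position_code")
}

#' @export
print.position_code <- function(x, ...) {
  cat(sprintf("<position %s: house %d, cage %d, group %d, nest %d>\n",
              format_position(x), x$house, x$cage, x$group, x$nest))
  invisible(x)
}

#' Parse an 8-digit position string
#'
#' @param uid exactly 8 decimal digits: house, cage, group, nest, two
#'   digits each.
#' @return a [position_code()].
#' @examples
#' parse_position("01012104")
#' @export
parse_position <- function(uid) {
  if (length(uid) != 1 || !is.character(uid) || !grepl("^[0-9]{8}$", uid)) {
    stop("uid must be a string of exactly 8 decimal digits", call. = FALSE)
  }
  position_code(as.integer(substr(uid, 1, 2)),
                as.integer(substr(uid, 3, 4)),
                as.integer(substr(uid, 5, 6)),
                as.integer(substr(uid, 7, 8)))
}

#' @rdname parse_position
#' @param code a [position_code()].
#' @export
format_position <- function(code) {
  stopifnot(inherits(code, "position_code"))
  sprintf("%02d%02d%02d%02d", code$house, code$cage, code$group, code$nest)
}

#' Embed a position code in an EAN-13 number
#'
#' The 8-digit position fills data digits 5-12 of the 13-digit code; a
#' fixed 4-digit prefix (default "2000", in the restricted-distribution
#' numbering space, so farm labels cannot collide with retail articles)
#' fills digits 1-4, and the 13th digit is the standard weighted-sum check
#' digit.
#'
#' @param code a [position_code()].
#' @param prefix 4-digit string prepended to the payload.
#' @return the 13-digit code as a string.
#' @examples
#' embed_in_ean13(position_code(1, 1, 21, 4))  # "2000010121045"
#' @export
embed_in_ean13 <- function(code, prefix = "2000") {
  if (!grepl("^[0-9]{4}$", prefix)) {
    stop("prefix must be a string of exactly 4 decimal digits", call. = FALSE)
  }
  data12 <- paste0(prefix, format_position(code))
  paste0(data12, ean13_check_digit(data12))
}

#' @rdname embed_in_ean13
#' @param ean a 13-digit EAN string with a valid check digit.
#' @export
extract_from_ean13 <- function(ean, prefix = "2000") {
  ean13_validate(ean)
  if (substr(ean, 1, 4) != prefix) {
    stop(sprintf("foreign barcode: prefix '%s' does not match expected '%s'",
                 substr(ean, 1, 4), prefix), call. = FALSE)
  }
  parse_position(substr(ean, 5, 12))
}
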