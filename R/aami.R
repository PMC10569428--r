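#' AAMI EC57 heartbeat classes
#'
#' The five-way beat grouping recommended by the Association for the
#' Advancement of Medical Instrumentation (AAMI, EC57): N (normal and
#' bundle-branch-block beats), S (supraventricular ectopic), V (ventricular
#' ectopic), F (fusion of ventricular and normal), Q (unknown or paced).
#'
#' @return Character vector of the five class labels, in reporting order.
#' @export
#' @examples
#' aami_classes()
aami_classes <- function() c("N", "S", "V", "F", "Q")

# MIT-BIH beat annotation symbol -> AAMI EC57 class
.aami_symbol_table <- c(
  "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N",
  "A" = "S", "a" = "S", "J" = "S", "S" = "S",
  "V" = "V", "E" = "V",
  "F" = "F",
  "/" = "Q", "f" = "Q", "Q" = "Q"
)

#' Map beat annotation symbols to AAMI classes
#'
#' Maps MIT-BIH single-character beat annotation codes onto the AAMI EC57
#' five-class grouping: N <- \{N, L, R, e, j\}, S <- \{A, a, J, S\},
#' V <- \{V, E\}, F <- \{F\}, Q <- \{/, f, Q\}.  Non-beat annotations
#' (rhythm changes such as \code{"+"}, signal-quality marks, etc.) and
#' unknown codes map to \code{NA}, meaning the annotation is skipped during
#' beat extraction.
#'
#' @param symbol Character vector of single-character annotation codes.
#' @return Character vector of AAMI class labels (\code{NA} = not a beat).
#' @export
#' @examples
#' aami_class(c("N", "A", "V", "+", "~"))
aami_class <- function(symbol) {
  out <- unname(.aami_symbol_table[symbol])
  out
}

# record id lists of the inter-patient evaluation protocol
.split_records <- list(
  DS1 = c("101", "106", "108", "109", "112", "114", "115", "116", "118",
          "119", "122", "124", "201", "203", "205", "207", "208", "209",
          "215", "220", "223", "230"),
  DS2 = c("100", "103", "105", "111", "113", "117", "121", "123", "200",
          "202", "210", "212", "213", "214", "219", "221", "222", "228",
          "231", "232", "233", "234"),
  DS1_2 = c("101", "106", "108", "109", "112", "114", "115", "116", "118",
            "119", "122"),
  DS1_3 = c("124", "201", "203", "205", "207", "208", "209", "215", "220",
            "223", "230")
)

#' Inter-patient record splits of the MIT-BIH arrhythmia database
#'
#' Returns the record ids of the standard inter-patient evaluation protocol:
#' \code{DS1} (22 training records) and \code{DS2} (22 test records) are
#' patient-disjoint; \code{DS1_2} and \code{DS1_3} partition \code{DS1} and
#' support reduced-sample experiments.
#'
#' @param name One of \code{"DS1"}, \code{"DS2"}, \code{"DS1_2"},
#'   \code{"DS1_3"}.
#' @return A tibble with columns \code{split} and \code{record_id}.
#' @export
#' @examples
#' aami_split("DS1_3")
aami_split <- function(name) {
  name <- match.arg(name, names(.split_records))
  tibble::tibble(split = name, record_id = .split_records[[name]])
}
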