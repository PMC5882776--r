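#' Chlorophenol congeners as chlorine ring-position sets
#'
#' A chlorophenol congener is identified by the set of ring positions bearing
#' chlorine, with the phenolic hydroxyl fixed at position 1. Valid positions
#' are 2--6; pentachlorophenol (PCP) is \{2,3,4,5,6\} and bare phenol is the
#' empty set. Names follow the field's convention: sorted locants joined by
#' commas plus a suffix keyed to the chlorine count (CP, DCP, TCP, TeCP),
#' with "PCP" and "phenol" as the special cases.
#'
#' Symmetry-equivalent position sets (e.g. \{2,3,4,5\} and its mirror
#' \{2,3,4,6\}) are deliberately not merged: microcosm studies distinguish
#' 2,3,4,5-TeCP from 2,3,4,6-TeCP analytically, and pathway bookkeeping must
#' preserve that distinction.
#'
#' @param positions Integer vector of distinct chlorine positions, a subset of
#'   2:6. May be empty (phenol).
#' @return `canonical_name()` returns the canonical name string;
#'   `parse_congener()` returns the sorted integer position vector.
#' @examples
#' canonical_name(c(3, 4, 5))   # "3,4,5-TCP"
#' canonical_name(2:6)          # "PCP"
#' parse_congener("3,5-DCP")    # c(3, 5)
#' @export
canonical_name <- function(positions) {
  positions <- check_positions(positions)
  n <- length(positions)
  if (n == 0L) return("phenol")
  if (n == 5L) return("PCP")
  suffix <- c("CP", "DCP", "TCP", "TeCP")[n]
  paste0(paste(positions, collapse = ","), "-", suffix)
}

#' @rdname canonical_name
#' @param name A congener name as produced by `canonical_name()`, e.g.
#'   `"2,3,4,5-TeCP"`, `"3-CP"`, `"PCP"`, `"phenol"`.
#' @export
parse_congener <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (identical(name, "phenol")) return(integer(0))
  if (identical(name, "PCP")) return(2:6)
  m <- regmatches(name, regexec("^([2-6](,[2-6])*)-(CP|DCP|TCP|TeCP)$", name))[[1]]
  if (length(m) == 0L) {
    abort(paste0("'", name, "' is not a valid chlorophenol congener name"),
          class = "pcpredox_invalid_congener")
  }
  positions <- as.integer(strsplit(m[2], ",")[[1]])
  positions <- check_positions(positions)
  expected <- c("CP", "DCP", "TCP", "TeCP")[length(positions)]
  if (!identical(m[4], expected)) {
    abort(paste0("'", name, "' has ", length(positions),
                 " locants but suffix -", m[4]),
          class = "pcpredox_invalid_congener")
  }
  positions
}

check_positions <- function(positions) {
  if (length(positions) == 0L) return(integer(0))
  positions <- as.integer(positions)
  if (anyNA(positions) || any(!positions %in% 2:6) || anyDuplicated(positions)) {
    abort("chlorine positions must be distinct integers in 2..6",
          class = "pcpredox_invalid_position")
  }
  sort(positions)
}

# Accept either a name or a position vector anywhere a congener is expected.
as_positions <- function(x) {
  if (is.character(x)) parse_congener(x) else check_positions(x)
}

#' Classify a ring position relative to the phenolic hydroxyl
#'
#' Positions 2 and 6 are *ortho*, 3 and 5 *meta*, and 4 *para* to the hydroxyl
#' at position 1. The class of the removed chlorine is what distinguishes the
#' known anaerobic PCP dechlorination routes.
#'
#' @param position Integer vector of ring positions in 2..6.
#' @return Character vector: `"ortho"`, `"meta"` or `"para"`.
#' @examples
#' position_class(c(2, 3, 4, 5, 6))
#' @export
position_class <- function(position) {
  position <- as.integer(position)
  if (anyNA(position) || any(!position %in% 2:6)) {
    abort("ring position must be in 2..6", class = "pcpredox_invalid_position")
  }
  unname(c(`2` = "ortho", `3` = "meta", `4` = "para",
           `5` = "meta", `6` = "ortho")[as.character(position)])
}

#' Identify a single reductive dechlorination step
#'
#' A valid step removes exactly one chlorine: the child's position set must be
#' the parent's minus one element. Returns the removed position and its
#' ortho/meta/para class.
#'
#' @param parent,child Congener names or chlorine position vectors.
#' @return A one-row tibble with columns `parent`, `child`,
#'   `removed_position`, `position_class`.
#' @examples
#' infer_step("PCP", "2,3,4,5-TeCP")   # removes 6, ortho
#' infer_step(c(3, 4, 5), c(3, 5))     # removes 4, para
#' @export
infer_step <- function(parent, child) {
  p <- as_positions(parent)
  c_ <- as_positions(child)
  if (length(p) != length(c_) + 1L || !all(c_ %in% p)) {
    abort(paste0(canonical_name(p), " -> ", canonical_name(c_),
                 " is not a single-chlorine-removal step"),
          class = "pcpredox_not_a_step")
  }
  removed <- setdiff(p, c_)
  tibble::tibble(
    parent = canonical_name(p),
    child = canonical_name(c_),
    removed_position = removed,
    position_class = position_class(removed)
  )
}

#' Classify an ordered dechlorination chain
#'
#' Validates that consecutive congeners differ by exactly one chlorine and
#' returns the per-step removed positions and their ortho/meta/para classes.
#' For the chain PCP, 2,3,4,5-TeCP, 3,4,5-TCP, 3,5-DCP, 3-CP the class
#' sequence is ortho, ortho, para, meta: dechlorination initiated at the
#' *ortho* position, then *para* and *meta*.
#'
#' @param chain A list (or character vector) of congener names or position
#'   vectors, ordered parent to terminus.
#' @return A tibble with one row per step (zero rows for a single-congener
#'   chain) and columns `step`, `parent`, `child`, `removed_position`,
#'   `position_class`.
#' @examples
#' infer_pathway(c("PCP", "2,3,4,5-TeCP", "3,4,5-TCP", "3,5-DCP", "3-CP"))
#' @export
infer_pathway <- function(chain) {
  if (!is.list(chain)) chain <- as.list(chain)
  empty <- tibble::tibble(step = integer(), parent = character(),
                          child = character(), removed_position = integer(),
                          position_class = character())
  if (length(chain) <= 1L) return(empty)
  steps <- purrr::map(seq_len(length(chain) - 1L), function(i) {
    tryCatch(
      infer_step(chain[[i]], chain[[i + 1L]]),
      pcpredox_not_a_step = function(e) {
        abort(paste0("invalid consecutive pair at step ", i, ": ",
                     conditionMessage(e)),
              class = "pcpredox_not_a_step")
      }
    )
  })
  dplyr::bind_rows(steps) |>
    dplyr::mutate(step = dplyr::row_number(), .before = 1)
}

#' Order congeners by first detection and classify the implied pathway
#'
#' Orders the congeners present in a tidy concentration table by the first
#' time each rises above a detection threshold (per-time replicate means are
#' used), then classifies the ordered chain with [infer_pathway()]. Congeners
#' never detected above the threshold are dropped.
#'
#' @param data A tidy data frame with columns `analyte`, `time_d`,
#'   `concentration`; congener analytes are those whose name parses via
#'   [parse_congener()].
#' @param threshold Detection threshold in the table's concentration unit
#'   (default 1, i.e. 1 uM for chlorophenols).
#' @return A list with `chain` (ordered congener names), `steps` (the
#'   [infer_pathway()] tibble) and `detected` (first-detection table). If no
#'   congener exceeds the threshold, `chain` is empty.
#' @export
detect_pathway <- function(data, threshold = 1) {
  stopifnot(is.data.frame(data))
  check_columns(data, c("analyte", "time_d", "concentration"))
  is_congener <- vapply(unique(data$analyte), function(a) {
    !inherits(tryCatch(parse_congener(a), error = function(e) e), "error")
  }, logical(1))
  congeners <- names(is_congener)[is_congener]
  above <- data |>
    dplyr::filter(.data$analyte %in% congeners) |>
    dplyr::summarise(concentration = mean(.data$concentration),
                     .by = c("analyte", "time_d")) |>
    dplyr::filter(.data$concentration > threshold)
  detected <- if (nrow(above) == 0L) {
    tibble::tibble(analyte = character(), first_detected_d = numeric())
  } else {
    above |>
      dplyr::summarise(first_detected_d = min(.data$time_d), .by = "analyte") |>
      # ties broken by chlorine count: heavier congeners precede their products
      dplyr::arrange(.data$first_detected_d,
                     -lengths(lapply(.data$analyte, parse_congener)))
  }
  chain <- detected$analyte
  steps <- if (length(chain) >= 2L) infer_pathway(chain) else infer_pathway(list())
  list(chain = chain, steps = steps, detected = detected)
}

#' All 32 chlorophenol position sets
#'
#' Enumerates every subset of \{2,...,6\} with its canonical name and chlorine
#' count. Useful for exhaustive pathway checks.
#'
#' @return A tibble with columns `name`, `n_cl` and list-column `positions`.
#' @export
all_congeners <- function() {
  sets <- unlist(lapply(0:5, function(k) {
    utils::combn(2:6, k, simplify = FALSE)
  }), recursive = FALSE)
  tibble::tibble(
    name = vapply(sets, canonical_name, character(1)),
    n_cl = lengths(sets),
    positions = sets
  )
}
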