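#' Memory-1 strategies of the repeated donation game
#'
#' A memory-1 strategy conditions its next move only on the previous round's
#' outcome. It is represented by four cooperation probabilities
#' `(p_cc, p_cd, p_dc, p_dd)`, indexed by the focal player's and the
#' co-player's previous actions. The 16 deterministic strategies (all entries
#' 0 or 1) are numbered `S_0` .. `S_15`: bit k of the id (k = 0 for CC, 1 for
#' CD, 2 for DC, 3 for DD) equal to 1 means Defect at that outcome, so that
#' `S_0` is AllC and `S_15` is AllD.
#'
#' @param id Integer in 0..15.
#' @return `strategy_from_id()` returns a numeric vector of length 4 with
#'   class `"memory1"`, carrying `id` and `label` attributes.
#' @examples
#' strategy_from_id(6) # Win-Stay Lose-Shift
#' @export
strategy_from_id <- function(id) {
  if (!is.numeric(id) || length(id) != 1L || is.na(id) ||
      id != round(id) || id < 0 || id > 15) {
    abort_invalid("`id` must be a single integer in 0..15.")
  }
  id <- as.integer(id)
  bits <- bitwAnd(bitwShiftR(id, 0:3), 1L) # 1 = Defect
  p <- 1 - bits
  new_memory1(p, id = id, label = strategy_label(id))
}

new_memory1 <- function(p, id = NA_integer_, label = NA_character_) {
  structure(as.numeric(p),
            names = c("p_cc", "p_cd", "p_dc", "p_dd"),
            id = id, label = label, class = "memory1")
}

strategy_names <- c(
  "0" = "AllC", "6" = "WSLS", "10" = "TFT", "14" = "GRIM", "15" = "AllD"
)

strategy_label <- function(id) {
  nm <- strategy_names[as.character(id)]
  if (is.na(nm)) sprintf("S_%d", id) else unname(nm)
}

#' @export
print.memory1 <- function(x, ...) {
  lbl <- attr(x, "label")
  id <- attr(x, "id")
  hdr <- if (!is.na(id)) sprintf("<memory1 strategy %s (S_%d)>", lbl, id)
         else "<memory1 strategy>"
  cat(hdr, "\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Parse a strategy specification
#'
#' Accepts a deterministic strategy id (`6` or `"6"`), a canonical name
#' (`"WSLS"`, `"TFT"`, `"GRIM"`, `"AllC"`, `"AllD"`, `"S_7"`), a 4-letter
#' action string in CC, CD, DC, DD order (`"CDDC"`), a numeric vector of four
#' cooperation probabilities, or a `memory1` object (returned unchanged).
#'
#' @param x Strategy specification.
#' @return A `memory1` strategy.
#' @examples
#' strategy("WSLS")
#' strategy("CDDC")
#' strategy(c(1, 0, 0, 1))
#' @export
strategy <- function(x) {
  if (inherits(x, "memory1")) return(x)
  if (is.numeric(x) && length(x) == 4L) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
      abort_invalid("strategy entries must be probabilities in [0, 1].")
    }
    det <- all(x %in% c(0, 1))
    if (det) {
      id <- sum((1 - x) * 2^(0:3))
      return(strategy_from_id(id))
    }
    return(new_memory1(x))
  }
  if (is.numeric(x) && length(x) == 1L) return(strategy_from_id(x))
  if (is.character(x) && length(x) == 1L) {
    up <- toupper(x)
    named <- names(strategy_names)[toupper(strategy_names) == up]
    if (length(named) == 1L) return(strategy_from_id(as.integer(named)))
    if (grepl("^S_?[0-9]+$", up)) {
      return(strategy_from_id(as.integer(sub("^S_?", "", up))))
    }
    if (grepl("^[0-9]+$", up)) return(strategy_from_id(as.integer(up)))
    if (grepl("^[CD]{4}$", up)) {
      p <- as.numeric(strsplit(up, "")[[1]] == "C")
      return(strategy(p))
    }
    abort_invalid(sprintf("cannot parse strategy specification '%s'.", x))
  }
  abort_invalid("unsupported strategy specification.")
}

#' All 16 deterministic memory-1 strategies as a tibble
#'
#' @return A tibble with one row per strategy: `id`, `label`, the action
#'   string `actions` (CC, CD, DC, DD order), and the four cooperation
#'   probabilities.
#' @examples
#' strategies()
#' @export
strategies <- function() {
  purrr::map_dfr(0:15, function(id) {
    s <- strategy_from_id(id)
    tibble::tibble(
      id = id,
      label = attr(s, "label"),
      actions = paste(ifelse(s == 1, "C", "D"), collapse = ""),
      p_cc = s[[1]], p_cd = s[[2]], p_dc = s[[3]], p_dd = s[[4]]
    )
  })
}

#' Apply implementation errors to a strategy
#'
#' With probability `e` a player's intended action is flipped, so the
#' effective strategy is `(1 - e) p + e (1 - p)` entrywise.
#'
#' @param p A strategy (anything [strategy()] accepts).
#' @param e Error probability in `[0, 1/2)`.
#' @return The effective `memory1` strategy.
#' @examples
#' apply_error(strategy("TFT"), 0.25)
#' @export
apply_error <- function(p, e) {
  p <- strategy(p)
  check_error_rate(e)
  new_memory1((1 - e) * as.numeric(p) + e * (1 - as.numeric(p)),
              id = attr(p, "id"), label = attr(p, "label"))
}

is_deterministic <- function(p) all(as.numeric(p) %in% c(0, 1))
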