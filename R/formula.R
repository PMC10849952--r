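# Molecular formula arithmetic.
#
# A formula is represented as a named integer vector of element counts
# (class "element_count").  Absent elements are count zero; counts are never
# negative.  Text form is Hill order: C, then H (with D immediately after H),
# then remaining symbols alphabetically.

#' Parse a molecular formula
#'
#' Parses text such as `"C28H55O8Cl"` into an element-count vector.  Symbols
#' must come from the embedded constants table ([known_elements()]); each may
#' be followed by an optional positive integer multiplicity.
#'
#' @param text A single formula string, e.g. `"C28H55O8Cl"`.
#' @return An object of class `element_count`: a named integer vector of
#'   counts, in Hill order.  Round-trips losslessly through [format()].
#' @examples
#' parse_formula("C28H55O8Cl")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  elements <- known_elements()
  counts <- integer(0)
  rest <- text
  while (nchar(rest) > 0L) {
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || m[1] == "") {
      stop("cannot parse formula '", text, "': unexpected token at '",
           rest, "'", call. = FALSE)
    }
    sym <- m[2]
    digits <- m[3]
    # A greedy two-letter match can swallow a following one-letter symbol's
    # position ("CH4" never, but guard symbols like "Cl" vs "C"): fall back
    # to the one-letter symbol when the two-letter one is unknown.
    if (!(sym %in% elements) && nchar(sym) == 2L &&
        substr(sym, 1L, 1L) %in% elements) {
      sym <- substr(sym, 1L, 1L)
      digits <- ""
    }
    if (!(sym %in% elements)) {
      stop("cannot parse formula '", text, "': unknown element symbol '",
           m[2], "'", call. = FALSE)
    }
    n <- if (digits == "") 1L else suppressWarnings(as.integer(digits))
    if (is.na(n) || n <= 0L) {
      stop("cannot parse formula '", text, "': invalid multiplicity '",
           digits, "' for ", sym, call. = FALSE)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    rest <- substr(rest, nchar(sym) + nchar(digits) + 1L, nchar(rest))
  }
  element_count(counts)
}

#' Construct an element-count vector
#'
#' @param counts Named integer vector or list (element symbol -> count).
#'   Duplicated symbols are summed; zero counts are dropped; negative counts
#'   are an error.
#' @return An `element_count` object in Hill order.
#' @export
element_count <- function(counts = integer(0)) {
  counts <- unlist(counts)
  if (length(counts) == 0L) {
    out <- integer(0)
    class(out) <- "element_count"
    return(out)
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("element counts must be named by element symbol", call. = FALSE)
  }
  bad <- setdiff(names(counts), known_elements())
  if (length(bad) > 0L) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  v <- as.integer(counts)
  names(v) <- names(counts)
  if (anyNA(v) || any(v < 0L)) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  v <- vapply(split(v, names(v)), sum, integer(1))
  v <- v[v > 0L]
  syms <- names(v)
  hill <- c(intersect(c("C", "H", "D"), syms),
            sort(setdiff(syms, c("C", "H", "D"))))
  out <- v[hill]
  names(out) <- hill
  class(out) <- "element_count"
  out
}

#' Format a formula in Hill notation
#'
#' @param x An `element_count`.
#' @param ... Unused.
#' @return A single string: C, H (and D), then remaining symbols
#'   alphabetically, each with its multiplicity when greater than one.
#' @export
format.element_count <- function(x, ...) {
  if (length(x) == 0L) return("")
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
as.character.element_count <- function(x, ...) format(x)

#' @export
print.element_count <- function(x, ...) {
  cat("<formula> ", format(x), "  (", sprintf("%.6f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' Add two formulas element-wise
#' @param a,b `element_count` objects (or formula strings).
#' @return Their element-wise sum as an `element_count`.
#' @export
formula_add <- function(a, b) {
  v <- c(unclass(as_element_count(a)), unclass(as_element_count(b)))
  if (length(v) == 0L) return(element_count())
  element_count(v)
}

#' Subtract formula `b` from `a` element-wise
#'
#' @param a,b `element_count` objects (or formula strings); every count of
#'   `b` must be covered by `a`.
#' @return The difference as an `element_count`.
#' @export
formula_subtract <- function(a, b) {
  av <- unclass(as_element_count(a))
  bv <- unclass(as_element_count(b))
  for (s in names(bv)) {
    have <- if (s %in% names(av)) av[[s]] else 0L
    if (have < bv[[s]]) {
      stop("cannot subtract ", s, bv[[s]], " from ", format(as_element_count(a)),
           call. = FALSE)
    }
    av[s] <- have - bv[[s]]
  }
  element_count(av)
}

# Count of a single element in a formula (0 when absent).
formula_count <- function(x, element) {
  v <- unclass(x)
  if (element %in% names(v)) v[[element]] else 0L
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum over elements of count times the lightest-isotope mass from the
#' embedded constants table.  Additive over formula union.
#'
#' @param formula An `element_count` or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")       # 18.010565
#' monoisotopic_mass("C28H55O8Cl")
#' @export
monoisotopic_mass <- function(formula) {
  formula <- as_element_count(formula)
  if (length(formula) == 0L) return(0.0)
  masses <- vapply(names(formula), .element_monoisotopic, numeric(1))
  sum(masses * unclass(formula))
}

#' Coerce to an element-count vector
#' @param x An `element_count` or a formula string.
#' @return An `element_count`.
#' @export
as_element_count <- function(x) {
  if (inherits(x, "element_count")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_formula(x))
  stop("cannot interpret as a molecular formula", call. = FALSE)
}
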