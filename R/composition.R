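#' Elemental compositions
#'
#' An `elem_comp` is a named integer vector of atom counts over C, H, N, O,
#' P and S. Compositions add and subtract with the usual operators;
#' subtraction that would produce a negative atom count is an error.
#'
#' @param C,H,N,O,P,S Non-negative integer atom counts.
#'
#' @return An object of class `elem_comp`.
#' @examples
#' elem_comp(C = 10, H = 13, N = 5, O = 4)  # adenosine
#' @export
elem_comp <- function(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0) {
  x <- c(C = C, H = H, N = N, O = O, P = P, S = S)
  if (any(x < 0)) stop("atom counts must be non-negative", call. = FALSE)
  x <- as.integer(round(x))
  names(x) <- .ELEMENTS
  structure(x, class = "elem_comp")
}

new_elem_comp <- function(x) {
  structure(as.integer(x[.ELEMENTS]), names = .ELEMENTS, class = "elem_comp")
}

#' @export
print.elem_comp <- function(x, ...) {
  cat("<elem_comp>", format_comp(x), "\n")
  invisible(x)
}

#' Format a composition as a molecular formula string
#'
#' @param comp An `elem_comp`.
#' @return A string such as `"C10H13N5O4"`.
#' @export
format_comp <- function(comp) {
  v <- unclass(comp)
  nz <- v[v > 0]
  if (length(nz) == 0) return("(empty)")
  paste0(names(nz), ifelse(nz > 1, nz, ""), collapse = "")
}

#' @export
Ops.elem_comp <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "==")) {
    stop("operation '", .Generic, "' not defined for elem_comp", call. = FALSE)
  }
  if (.Generic == "==") return(all(unclass(e1) == unclass(e2)))
  out <- get(.Generic)(unclass(e1), unclass(e2))
  if (any(out < 0)) {
    stop("composition subtraction yields negative atom counts", call. = FALSE)
  }
  new_elem_comp(out)
}

comp_scale <- function(comp, k) {
  new_elem_comp(unclass(comp) * as.integer(k))
}

is_empty_comp <- function(comp) sum(comp) == 0L

#' Neutral mass of an elemental composition
#'
#' Monoisotopic mass uses exact masses of the lightest isotopes; average mass
#' uses conventional standard atomic weights (the set under which printed
#' average masses of synthetic guides reproduce to < 0.02 Da).
#'
#' @param comp An `elem_comp`.
#' @param mode `"monoisotopic"` or `"average"`.
#' @return Mass in Da.
#' @examples
#' neutral_mass(elem_comp(C = 10, H = 13, N = 5, O = 4))  # adenosine, mono
#' @export
neutral_mass <- function(comp, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  w <- if (mode == "monoisotopic") .MONO_MASS else .AVG_MASS
  sum(unclass(comp) * w[.ELEMENTS])
}
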