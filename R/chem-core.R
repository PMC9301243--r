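# Exact molecular-formula arithmetic: parsing, monoisotopic mass,
# adduct m/z, ppm error.  All mass math in the package funnels through here.

# Monoisotopic masses (Da) of the most abundant isotope, IUPAC/CODATA,
# >= 6 decimal places.  C-12 defines the scale exactly.
.element_masses <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

#: elementary particle masses (Da)
.proton_mass   <- 1.007276466879
.electron_mass <- 0.000548579909

#' Construct an element-count object
#'
#' The atom-level currency of all mass arithmetic: a named vector of
#' non-negative integer element counts plus a net elementary charge.
#' Supported elements are C, H, N, O, P and S, which cover flavonoid
#' aglycones and their glycosyl/acyl decorations.
#'
#' @param counts Named integer vector, names are element symbols.
#' @param charge Integer net charge in elementary charges (e.g. `+1L`
#'   for a flavylium cation).
#' @return An object of class `element_counts`.
#' @examples
#' element_counts(c(C = 15, H = 10, O = 4))
#' @export
element_counts <- function(counts = integer(), charge = 0L) {
  counts <- counts[counts != 0]
  if (length(counts)) {
    bad <- setdiff(names(counts), names(.element_masses))
    if (length(bad))
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    if (any(counts < 0))
      stop("element counts must be non-negative")
    if (any(counts != round(counts)))
      stop("element counts must be integers")
  }
  if (length(counts)) {
    ord <- order(match(names(counts), names(.element_masses)))
    counts <- stats::setNames(as.integer(counts)[ord], names(counts)[ord])
  } else {
    counts <- stats::setNames(integer(0), character(0))
  }
  structure(list(counts = counts, charge = as.integer(charge)),
            class = "element_counts")
}

#' Parse a molecular formula string
#'
#' Grammar: one or more `Element`/`count` pairs (count defaults to 1),
#' optionally followed by trailing `+` / `-` charge signs, one per
#' elementary charge.  `"C22H23O11+"` parses to 22 C, 23 H, 11 O with
#' charge +1 (a flavylium-type native cation).
#'
#' @param text A single formula string such as `"C15H10O4"`.
#' @return An [element_counts()] object.
#' @examples
#' parse_formula("C15H10O4")       # daidzein
#' parse_formula("C22H23O11+")     # peonidin glucoside cation
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  body <- sub("[+−-]+$", "", text)
  tail <- substring(text, nchar(body) + 1L)
  charge <- 0L
  if (nzchar(tail)) {
    signs <- strsplit(tail, "")[[1]]
    charge <- sum(signs == "+") - sum(signs %in% c("-", "−"))
  }
  if (!nzchar(body)) stop("malformed formula: ", text)
  toks <- regmatches(body, gregexpr("([A-Z][a-z]?)([0-9]*)", body))[[1]]
  if (sum(nchar(toks)) != nchar(body))
    stop("malformed formula: ", text)
  counts <- integer(0)
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(.element_masses))
      stop("unknown element symbol: ", sym)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  element_counts(counts, charge)
}

#' Format an element-count object as a formula string
#'
#' Hill-order output (C, H, then remaining elements alphabetically) with
#' trailing charge signs, the convention used for the packaged library.
#'
#' @param f An [element_counts()] object.
#' @return A formula string.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "element_counts"))
  cnt <- f$counts
  ord <- c(intersect(c("C", "H"), names(cnt)),
           sort(setdiff(names(cnt), c("C", "H"))))
  body <- paste0(vapply(ord, function(s)
    paste0(s, if (cnt[[s]] != 1L) cnt[[s]] else ""), ""), collapse = "")
  sign <- if (f$charge > 0) strrep("+", f$charge)
          else if (f$charge < 0) strrep("-", -f$charge) else ""
  paste0(body, sign)
}

#' @export
print.element_counts <- function(x, ...) {
  cat("<element_counts> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Element-wise formula addition and subtraction
#'
#' Subtraction that would drive any element count negative is an error:
#' a neutral loss can never remove atoms that are not there.
#'
#' @param a,b [element_counts()] objects.
#' @return An [element_counts()] object.
#' @export
formula_add <- function(a, b) {
  stopifnot(inherits(a, "element_counts"), inherits(b, "element_counts"))
  syms <- union(names(a$counts), names(b$counts))
  cnt <- vapply(syms, function(s)
    (if (s %in% names(a$counts)) a$counts[[s]] else 0L) +
    (if (s %in% names(b$counts)) b$counts[[s]] else 0L), integer(1))
  element_counts(stats::setNames(cnt, syms), a$charge + b$charge)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  stopifnot(inherits(a, "element_counts"), inherits(b, "element_counts"))
  syms <- union(names(a$counts), names(b$counts))
  cnt <- vapply(syms, function(s)
    (if (s %in% names(a$counts)) a$counts[[s]] else 0L) -
    (if (s %in% names(b$counts)) b$counts[[s]] else 0L), integer(1))
  if (any(cnt < 0))
    stop("subtraction yields negative element count")
  element_counts(stats::setNames(cnt, syms), a$charge - b$charge)
}

#' @export
`+.element_counts` <- function(e1, e2) formula_add(e1, e2)

#' @export
`-.element_counts` <- function(e1, e2) formula_subtract(e1, e2)

#' Neutral-atom monoisotopic mass
#'
#' Sum over elements of count times the most-abundant-isotope mass.
#' The charge field is ignored here: this is the neutral-atom sum; use
#' [adduct_mz()] (native-cation rule) for charged-species m/z.
#'
#' @param f An [element_counts()] object or a formula string.
#' @return Mass in Da (0 for the empty formula).
#' @examples
#' monoisotopic_mass("C15H10O4")  # 254.0579
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "element_counts"))
  if (!length(f$counts)) return(0)
  sum(f$counts * .element_masses[names(f$counts)])
}

#' Adduct / cation m/z from a neutral monoisotopic mass
#'
#' Positive-mode rules only: protonation `[M+H]+` adds z proton masses
#' (1.007276 Da each); a native cation `M+` (permanently charged
#' species such as anthocyanidin flavylium ions) subtracts z electron
#' masses from the neutral-atom sum of its formula.
#'
#' @param m Neutral(-atom) monoisotopic mass in Da.
#' @param adduct `"[M+H]+"` or `"M+"`.
#' @param z Positive integer charge, default 1.
#' @return m/z in Th.
#' @examples
#' adduct_mz(254.0579)  # 255.0652, protonated daidzein
#' @export
adduct_mz <- function(m, adduct = c("[M+H]+", "M+"), z = 1L) {
  adduct <- match.arg(adduct)
  if (z < 1 || z != round(z)) stop("z must be a positive integer")
  switch(adduct,
    "[M+H]+" = (m + z * .proton_mass) / z,
    "M+"     = (m - z * .electron_mass) / z
  )
}

#' Signed relative mass error in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param observed,theoretical m/z or mass values; `theoretical` must be
#'   strictly positive.
#' @return Signed ppm error (vectorised).
#' @examples
#' ppm_error(255.0678, 255.0652)  # ~ +10.2 ppm, fails a 10-ppm gate
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be > 0")
  1e6 * (observed - theoretical) / theoretical
}
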