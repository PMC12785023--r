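# Tentative MS1 annotation: mass-tolerance lookup of query m/z values
# against a local table of elemental formulas with adduct arithmetic.
# MS1-only matching cannot identify compounds; every hit is tentative.

# Monoisotopic atomic masses, Da (IUPAC/AME2020 values).
MONOISOTOPIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100,
  Na = 22.9897692809,
  K = 38.96370668,
  Cl = 34.96885268)

PROTON_MASS <- 1.00727646688
ELECTRON_MASS <- 0.00054857990

# Ion-mass shifts relative to the neutral monoisotopic mass M.
ADDUCT_SHIFTS <- list(
  "[M+H]+"  = list(shift = PROTON_MASS, polarity = "positive"),
  "[M-H]-"  = list(shift = -PROTON_MASS, polarity = "negative"),
  "[M+Na]+" = list(shift = MONOISOTOPIC_MASS[["Na"]] - ELECTRON_MASS,
                   polarity = "positive"),
  "[M+K]+"  = list(shift = MONOISOTOPIC_MASS[["K"]] - ELECTRON_MASS,
                   polarity = "positive"))

#' Monoisotopic mass of an elemental formula
#'
#' Parses a Hill-style formula (element symbols with optional counts, e.g.
#' `"C9H16N3O13P3"`) and sums standard monoisotopic atomic masses.
#'
#' @param formula formula string over C, H, N, O, P, S, Na, K, Cl.
#' @return the neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula))
    stop("empty formula")
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (nzchar(gsub("[A-Z][a-z]?[0-9]*", "", formula)))
    stop("unparseable formula: ", formula)
  total <- 0
  for (p in parts) {
    elem <- gsub("[0-9]+", "", p)
    count <- sub("^[A-Za-z]+", "", p)
    count <- if (nzchar(count)) as.integer(count) else 1L
    if (!elem %in% names(MONOISOTOPIC_MASS))
      stop("unknown element '", elem, "' in formula ", formula)
    total <- total + MONOISOTOPIC_MASS[[elem]] * count
  }
  total
}

#' Theoretical m/z of an adduct ion
#'
#' @param mass neutral monoisotopic mass in Da, positive.
#' @param adduct one of `"[M+H]+"`, `"[M-H]-"`, `"[M+Na]+"`, `"[M+K]+"`.
#' @return theoretical m/z in Da of the singly charged ion.
#' @export
theoretical_mz <- function(mass, adduct) {
  if (!is.numeric(mass) || mass <= 0) stop("mass must be positive")
  if (!adduct %in% names(ADDUCT_SHIFTS))
    stop("unsupported adduct: ", adduct)
  mass + ADDUCT_SHIFTS[[adduct]]$shift
}

#' Load the shipped annotation table
#'
#' A small curated tab-separated table (name, formula, class) of metabolites
#' relevant to low-mass-range tissue imaging: nucleotides (including dCTP),
#' common glycerophospholipids, fatty acids and sugars. User tables in the
#' same three-column format can be passed to [annotate()] instead.
#'
#' @param path optional path to a custom TSV; defaults to the shipped one.
#' @return data.frame with columns `name`, `formula`, `class`.
#' @export
load_annotation_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "metabolite_table.tsv",
                        package = "msimargin", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Tentative annotation of a query m/z
#'
#' Returns every (table entry, adduct) pair whose theoretical m/z lies
#' within the mass tolerance of the query, restricted to adducts matching
#' the ionization mode's polarity, sorted by ascending mass error. All
#' matches are tentative: MS1 mass alone cannot identify a molecular
#' species.
#'
#' @param query_mz query mass-to-charge in Da.
#' @param mode `"positive"` or `"negative"`.
#' @param table annotation table as from [load_annotation_table()].
#' @param tolerance mass tolerance in Da (default 0.1, i.e. +/- 0.1 Da).
#' @return data.frame of hits (possibly 0 rows): `name`, `formula`,
#'   `class`, `adduct`, `theoretical_mz`, `delta`, `tentative`.
#' @export
annotate <- function(query_mz, mode = c("positive", "negative"),
                     table = load_annotation_table(), tolerance = 0.1) {
  mode <- match.arg(mode)
  if (tolerance <= 0) stop("tolerance must be positive")
  adducts <- names(Filter(function(a) a$polarity == mode, ADDUCT_SHIFTS))
  masses <- vapply(table$formula, monoisotopic_mass, numeric(1),
                   USE.NAMES = FALSE)
  hits <- list()
  for (ad in adducts) {
    tmz <- vapply(masses, theoretical_mz, numeric(1), adduct = ad)
    delta <- abs(query_mz - tmz)
    ok <- delta <= tolerance
    if (any(ok))
      hits[[ad]] <- data.frame(
        name = table$name[ok], formula = table$formula[ok],
        class = table$class[ok], adduct = ad,
        theoretical_mz = tmz[ok], delta = delta[ok],
        tentative = TRUE)
  }
  if (length(hits) == 0L)
    return(data.frame(name = character(), formula = character(),
                      class = character(), adduct = character(),
                      theoretical_mz = numeric(), delta = numeric(),
                      tentative = logical()))
  out <- do.call(rbind, hits)
  out <- out[order(out$delta), , drop = FALSE]
  rownames(out) <- NULL
  out
}
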