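# Elemental-formula arithmetic, monoisotopic masses, ion species, the
# biotransformation catalogue and feature naming.

# IUPAC monoisotopic masses of the lightest isotope, >= 6 decimals.
.MONO_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Cl = 34.96885268,
  Na = 22.9897692809,
  K  = 38.96370668
)

#' Mass constants
#'
#' \code{protonMass} is the mass of the proton (Da), used for protonation and
#' deprotonation arithmetic in both polarities (electron mass is ignored
#' throughout, standard small-molecule practice at < 5 ppm tolerances).
#' \code{c13Spacing} is the 13C-12C mass difference (Da) used for
#' isotopologue spacing.
#'
#' @return a numeric scalar (Da).
#' @export
protonMass <- function() 1.00727646688

#' @rdname protonMass
#' @export
c13Spacing <- function() 1.003355

#' Parse an elemental formula in Hill notation
#'
#' Accepts strings such as \code{"C14H19NO"} or \code{"C17H25NO"}. Element
#' symbols must be among C, H, N, O, S, P, Cl, Na, K; an unknown symbol is
#' rejected with an error naming it. Omitted counts default to 1. The empty
#' string is the empty formula.
#'
#' @param x formula string, or an already-parsed named integer vector (then
#'   returned validated).
#' @return named integer vector of element counts (class "ElementalFormula");
#'   elements in input order, zero counts dropped.
#' @examples
#' parseFormula("C14H19NO")
#' @export
parseFormula <- function(x) {
  if (is.numeric(x)) {
    counts <- x
    bad <- setdiff(names(counts), names(.MONO_MASS))
    if (length(bad))
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    if (any(counts < 0)) stop("element counts must be non-negative")
    counts <- counts[counts > 0]
    storage.mode(counts) <- "integer"
    class(counts) <- "ElementalFormula"
    return(counts)
  }
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (!nzchar(x)) {
    out <- integer(0)
    class(out) <- "ElementalFormula"
    return(out)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x))
    stop("cannot parse formula: '", x, "'")
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Za-z]+", "", toks)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  bad <- setdiff(sym, names(.MONO_MASS))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(unique(bad), collapse = ", "))
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[counts > 0]
  class(counts) <- "ElementalFormula"
  counts
}

#' Render a parsed formula back to a string
#' @param f named integer vector as returned by [parseFormula()].
#' @return character scalar in the element order of \code{f}.
#' @export
formulaToString <- function(f) {
  if (!length(f)) return("")
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

#' Combine two formulas
#' @param a,b formulas (strings or parsed vectors).
#' @return parsed formula with summed counts.
#' @export
addFormulas <- function(a, b) {
  a <- parseFormula(a); b <- parseFormula(b)
  el <- union(names(a), names(b))
  out <- stats::setNames(integer(length(el)), el)
  out[names(a)] <- out[names(a)] + unclass(a)
  out[names(b)] <- out[names(b)] + unclass(b)
  parseFormula(out)
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum over elements of count times the lightest-isotope mass.
#'
#' @param formula a formula string or parsed formula.
#' @return mass in Da.
#' @examples
#' monoisotopicMass("C14H19NO") # 217.146664
#' @export
monoisotopicMass <- function(formula) {
  f <- parseFormula(formula)
  if (!length(f)) return(0)
  sum(.MONO_MASS[names(f)] * unclass(f))
}

# ---- signed element deltas (biotransformation arithmetic) -------------------

# Parse a signed delta string like "+H2", "-C4H6", "+O-H2" into a named
# numeric vector of signed counts.
.parseDelta <- function(delta) {
  delta <- gsub("[[:space:]]", "", delta)
  if (!nzchar(delta)) return(stats::setNames(numeric(0), character(0)))
  if (!grepl("^[+-]", delta)) delta <- paste0("+", delta)
  chunks <- regmatches(delta, gregexpr("[+-][A-Za-z0-9]+", delta))[[1]]
  if (sum(nchar(chunks)) != nchar(delta))
    stop("cannot parse delta formula: '", delta, "'")
  out <- stats::setNames(numeric(0), character(0))
  for (ch in chunks) {
    sgn <- if (substr(ch, 1, 1) == "+") 1 else -1
    f <- parseFormula(substring(ch, 2))
    for (el in names(f)) {
      cur <- if (el %in% names(out)) out[[el]] else 0
      out[el] <- cur + sgn * f[[el]]
    }
  }
  out
}

#' Mass change of a signed element delta
#'
#' @param delta signed delta string, e.g. \code{"+O-H2"} (net gain of one
#'   oxygen and loss of two hydrogens, the oxo- shift).
#' @return signed mass change in Da (monoisotopic mass of the gained part
#'   minus that of the lost part).
#' @examples
#' deltaMass("+H2")    #  2.015650
#' deltaMass("-C4H6")  # -54.046950
#' @export
deltaMass <- function(delta) {
  d <- .parseDelta(delta)
  if (!length(d)) return(0)
  sum(.MONO_MASS[names(d)] * d)
}

#' Apply a signed element delta to a formula
#' @param formula formula string or parsed formula.
#' @param delta signed delta string.
#' @return parsed formula after the change; negative resulting counts are an
#'   error (the transformation does not apply to that composition).
#' @export
applyDelta <- function(formula, delta) {
  f <- parseFormula(formula)
  d <- .parseDelta(delta)
  el <- union(names(f), names(d))
  out <- stats::setNames(numeric(length(el)), el)
  out[names(f)] <- out[names(f)] + unclass(f)
  out[names(d)] <- out[names(d)] + d
  if (any(out < 0))
    stop("delta '", delta, "' does not apply to formula '",
         formulaToString(f), "'")
  parseFormula(out)
}

# ---- ion species ------------------------------------------------------------

#' Ionic species description
#'
#' Describes an ion of the form [nM + pH + X]z: \code{multiplicity} n (the
#' number of neutral molecules), \code{protons} p (signed; -1 for
#' deprotonation), \code{extra} further atoms gained (e.g. one Cl for the
#' chloride-bridged dimer adduct), and the signed \code{charge}.
#'
#' @slot multiplicity integer >= 1.
#' @slot protons signed integer count of protons gained/lost.
#' @slot extra formula string of additional atoms (may be "").
#' @slot charge signed integer, nonzero.
#' @slot label display label such as "[M+H]+".
#' @export
setClass("IonSpecies",
  representation(multiplicity = "integer", protons = "integer",
                 extra = "character", charge = "integer",
                 label = "character"),
  prototype(multiplicity = 1L, protons = 1L, extra = "", charge = 1L,
            label = "[M+H]+"))

setValidity("IonSpecies", function(object) {
  msg <- character()
  if (object@multiplicity < 1L) msg <- c(msg, "multiplicity must be >= 1")
  if (object@charge == 0L) msg <- c(msg, "charge must be nonzero")
  if (length(msg)) msg else TRUE
})

#' @describeIn IonSpecies-class constructor
#' @param multiplicity,protons,extra,charge,label see slots.
#' @export
ionSpecies <- function(multiplicity = 1L, protons = 1L, extra = "",
                       charge = 1L, label = NA_character_) {
  if (is.na(label)) {
    core <- paste0(if (multiplicity > 1L) multiplicity else "", "M")
    if (protons != 0L)
      core <- paste0(core, if (protons > 0L) "+" else "-",
                     if (abs(protons) > 1L) abs(protons) else "", "H")
    if (nzchar(extra)) core <- paste0(core, "+", extra)
    label <- paste0("[", core, "]", if (charge > 0L) "+" else "-")
  }
  new("IonSpecies", multiplicity = as.integer(multiplicity),
      protons = as.integer(protons), extra = extra,
      charge = as.integer(charge), label = label)
}

setMethod("show", "IonSpecies", function(object) {
  cat("IonSpecies ", object@label, " (n=", object@multiplicity,
      ", protons=", object@protons,
      if (nzchar(object@extra)) paste0(", +", object@extra) else "",
      ", z=", object@charge, ")\n", sep = "")
})

#' Parse a bracketed adduct notation
#'
#' Understands labels of the form \code{"[nM+aH+X-Y]z+"} such as
#' \code{"[M+H]+"}, \code{"[M-H]-"}, \code{"[M+Na]+"} or
#' \code{"[2M+2H+Cl]+"}. \code{H} tokens are interpreted as protons; all
#' other element tokens are extra neutral atoms.
#'
#' @param label adduct string.
#' @return an \linkS4class{IonSpecies}.
#' @export
parseIonSpecies <- function(label) {
  m <- regmatches(label,
    regexec("^\\[([0-9]*)M((?:[+-][0-9]*[A-Z][a-z]?[0-9]*)*)\\]([0-9]*)([+-])$",
            label))[[1]]
  if (!length(m)) stop("cannot parse ion species label: '", label, "'")
  mult <- if (nzchar(m[2])) as.integer(m[2]) else 1L
  zmag <- if (nzchar(m[4])) as.integer(m[4]) else 1L
  charge <- if (m[5] == "+") zmag else -zmag
  protons <- 0L
  extra <- integer(0)
  if (nzchar(m[3])) {
    toks <- regmatches(m[3], gregexpr("[+-][0-9]*[A-Z][a-z]?[0-9]*", m[3]))[[1]]
    for (tk in toks) {
      sgn <- if (substr(tk, 1, 1) == "+") 1L else -1L
      body <- substring(tk, 2)
      pre <- regmatches(body, regexec("^([0-9]*)([A-Z][a-z]?)([0-9]*)$", body))[[1]]
      nrep <- if (nzchar(pre[2])) as.integer(pre[2]) else 1L
      el <- pre[3]
      nsub <- if (nzchar(pre[4])) as.integer(pre[4]) else 1L
      count <- nrep * nsub
      if (el == "H") {
        protons <- protons + sgn * count
      } else {
        if (sgn < 0) stop("loss of non-hydrogen atoms not supported: ", label)
        cur <- if (el %in% names(extra)) extra[[el]] else 0L
        extra[el] <- cur + count
      }
    }
  }
  extraStr <- if (length(extra))
    formulaToString(parseFormula(extra)) else ""
  ionSpecies(mult, protons, extraStr, charge, label = label)
}

#' m/z of an ion species
#'
#' \code{(n * M + p * protonMass() + mass(extra)) / |z|}. Electron mass is
#' ignored; the proton mass is used in both polarities.
#'
#' @param neutralMass monoisotopic mass of the neutral molecule (Da).
#' @param species an \linkS4class{IonSpecies} or an adduct label string.
#' @return m/z value.
#' @examples
#' ionMz(monoisotopicMass("C14H19NO"), "[M+H]+")      # 218.15394
#' ionMz(monoisotopicMass("C14H19NO"), "[2M+2H+Cl]+") # 471.27673
#' @export
ionMz <- function(neutralMass, species) {
  if (is.character(species)) species <- parseIonSpecies(species)
  stopifnot(is(species, "IonSpecies"))
  if (species@charge == 0L) stop("ion species must carry a nonzero charge")
  extraMass <- if (nzchar(species@extra))
    monoisotopicMass(species@extra) else 0
  (species@multiplicity * neutralMass + species@protons * protonMass() +
     extraMass) / abs(species@charge)
}

#' Built-in adduct catalogue
#'
#' Ion species commonly observed in positive- and negative-mode ESI of small
#' molecules, including the chloride-bridged proton-bound dimer
#' \code{[2M+2H+Cl]+}.
#'
#' @return named list of \linkS4class{IonSpecies}.
#' @export
builtinAdducts <- function() {
  labs <- c("[M+H]+", "[M+Na]+", "[M+K]+", "[2M+H]+", "[2M+2H+Cl]+",
            "[M-H]-")
  stats::setNames(lapply(labs, parseIonSpecies), labs)
}

# ---- biotransformation catalogue --------------------------------------------

#' Built-in biotransformation and in-source reaction catalogue
#'
#' Catalogue of mass-shift rules relating a precursor ion to a product ion.
#' \code{kind} distinguishes enzymatic biotransformations ("metabolic") from
#' shifts that human enzymes cannot perform and that arise in the ion source
#' or during sample handling ("artifact"); the distinction drives the origin
#' classification ladder. \code{mass_delta} is derived from the element
#' delta; the two are kept consistent to < 1e-6 Da.
#'
#' Rules: dihydro- (+H2, carbonyl reduction), dehydro- (-H2, pyrrolidine
#' oxidation, typically in-source), HO- (+O, hydroxylation), di-HO- (+O2),
#' oxo- (+O-H2, lactam formation), dihydro-HO- (+H2+O), dihydro-oxo- (net
#' +O), oxo-HO- (+O2-H2), N,N-dealkyl- (-C4H6, pyrrolidine ring loss),
#' imido- (+NH-O, imide artifact of dehydro species), cyano- (+CHN, HCN
#' addition from acetonitrile).
#'
#' @return data.frame with columns name, delta, mass_delta, kind.
#' @export
builtinTransformations <- function() {
  rules <- data.frame(
    name = c("dihydro-", "dehydro-", "HO-", "di-HO-", "oxo-",
             "dihydro-HO-", "dihydro-oxo-", "oxo-HO-", "N,N-dealkyl-",
             "imido-", "cyano-"),
    delta = c("+H2", "-H2", "+O", "+O2", "+O-H2",
              "+H2+O", "+O", "+O2-H2", "-C4H6",
              "+HN-O", "+CHN"),
    kind = c("metabolic", "artifact", "metabolic", "metabolic", "metabolic",
             "metabolic", "metabolic", "metabolic", "metabolic",
             "artifact", "artifact"),
    stringsAsFactors = FALSE
  )
  rules$mass_delta <- vapply(rules$delta, deltaMass, numeric(1))
  rules[, c("name", "delta", "mass_delta", "kind")]
}

#' Apply a transformation rule to an ion m/z
#' @param mz precursor ion m/z.
#' @param rule a row of the catalogue (list/data.frame with
#'   \code{mass_delta}), a rule name from [builtinTransformations()], or a
#'   signed delta string.
#' @param charge absolute charge of the ion (default 1).
#' @return product ion m/z.
#' @export
applyTransformation <- function(mz, rule, charge = 1L) {
  if (is.character(rule)) {
    cat <- builtinTransformations()
    hit <- match(rule, cat$name)
    md <- if (!is.na(hit)) cat$mass_delta[hit] else deltaMass(rule)
  } else md <- rule$mass_delta
  mz + md / abs(charge)
}

#' Read/write a transformation catalogue as CSV
#'
#' The serialized form has columns \code{name}, \code{delta} (signed element
#' delta) and \code{mass_delta}; \code{kind} is optional and defaults to
#' "metabolic". On reading, \code{mass_delta} is recomputed from
#' \code{delta} and a mismatch beyond 1e-6 Da is an error.
#'
#' @param path file path.
#' @param rules catalogue data.frame (for writing).
#' @return the catalogue data.frame (reading), invisibly \code{path}
#'   (writing).
#' @export
readTransformations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "delta") %in% names(df)))
  recomputed <- vapply(df$delta, deltaMass, numeric(1))
  if ("mass_delta" %in% names(df) &&
      any(abs(df$mass_delta - recomputed) > 1e-6))
    stop("mass_delta inconsistent with element delta in ", path)
  df$mass_delta <- recomputed
  if (!"kind" %in% names(df)) df$kind <- "metabolic"
  df[, c("name", "delta", "mass_delta", "kind")]
}

#' @rdname readTransformations
#' @export
writeTransformations <- function(rules, path) {
  utils::write.csv(rules, path, row.names = FALSE)
  invisible(path)
}

# ---- feature naming ---------------------------------------------------------

.roundHalfUp <- function(x) floor(x + 0.5)

#' Feature name from m/z and retention time
#'
#' Features are named "M" followed by the rounded m/z and "T" followed by the
#' rounded retention time in seconds, e.g. \code{M218T216}. Rounding is
#' half-up.
#'
#' @param mz m/z (> 0).
#' @param rt retention time in seconds (>= 0).
#' @return character vector of names.
#' @examples
#' featureName(218.1540, 216.4) # "M218T216"
#' @export
featureName <- function(mz, rt) {
  if (any(mz <= 0)) stop("mz must be positive")
  if (any(rt < 0)) stop("rt must be non-negative")
  paste0("M", .roundHalfUp(mz), "T", .roundHalfUp(rt))
}

#' Parse a feature name back into its integer parts
#' @param name feature names like "M218T216".
#' @return data.frame with integer columns mass_part, rt_part.
#' @export
parseFeatureName <- function(name) {
  ok <- grepl("^M[0-9]+T[0-9]+$", name)
  if (!all(ok)) stop("malformed feature name: ", name[!ok][1])
  data.frame(
    mass_part = as.integer(sub("^M([0-9]+)T[0-9]+$", "\\1", name)),
    rt_part = as.integer(sub("^M[0-9]+T([0-9]+)$", "\\1", name)))
}

#' Relative mass error in parts per million
#' @param measured,expected m/z values.
#' @return signed ppm error of \code{measured} against \code{expected}.
#' @export
ppmError <- function(measured, expected) {
  (measured - expected) / expected * 1e6
}
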