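# Monoisotopic masses of the principal isotope of each element (Da), and the
# electron mass. IUPAC/CODATA values, >= 7 decimals. Comparisons are always on
# unrounded values; rounding to 4 decimals happens only for display.

.ELECTRON_MASS <- 0.00054857990946

.MONOISOTOPIC_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  Na = 22.9897692809,
  Mg = 23.9850417000,
  P  = 30.9737616300,
  S  = 31.9720710015,
  Cl = 34.9688527100,
  K  = 38.9637064900,
  Ca = 39.9625909800,
  F  = 18.9984031630,
  Si = 27.9769265350,
  Fe = 55.9349375000,
  Se = 79.9165218000,
  Br = 78.9183376000,
  I  = 126.9044730000
)

.PROTON_MASS <- .MONOISOTOPIC_MASS[["H"]] - .ELECTRON_MASS

# ESI adduct registry: observed m/z = multiplier * M + mass_delta. The deltas
# carry the electron correction: protonation adds a bare proton, +Na and the
# intrinsic cation [M]+ lose one electron, the formate anion CHO2- keeps its
# extra electron. This is the unique convention reproducing the reference
# compound table to 4 decimals.
.ADDUCTS <- list(
  "[M+H]+"    = list(multiplier = 1L, polarity = "positive",
                     mass_delta = .PROTON_MASS),
  "[M-H]-"    = list(multiplier = 1L, polarity = "negative",
                     mass_delta = -.PROTON_MASS),
  "[M+Na]+"   = list(multiplier = 1L, polarity = "positive",
                     mass_delta = .MONOISOTOPIC_MASS[["Na"]] - .ELECTRON_MASS),
  "[M+COOH]-" = list(multiplier = 1L, polarity = "negative",
                     mass_delta = .MONOISOTOPIC_MASS[["C"]] +
                       .MONOISOTOPIC_MASS[["H"]] +
                       2 * .MONOISOTOPIC_MASS[["O"]] + .ELECTRON_MASS),
  "[2M-H]-"   = list(multiplier = 2L, polarity = "negative",
                     mass_delta = -.PROTON_MASS),
  "[M]+"      = list(multiplier = 1L, polarity = "positive",
                     mass_delta = -.ELECTRON_MASS)
)

# Map unicode minus / en-dash and spacing variants onto the canonical ASCII
# adduct labels ("[M - H]-", "[M−H]−", ... all accepted).
normalize_adduct_name <- function(name) {
  x <- gsub("[−–—]", "-", name)
  x <- gsub("[[:space:]]", "", x)
  x <- sub("^\\[M\\+HCOO\\]-$", "[M+COOH]-", x)
  x
}

#' Supported ESI adduct specifications
#'
#' Returns the adduct registry used by [adduct_mz()]: for each supported
#' adduct label, the molecular multiplier `k`, the signed mass delta added to
#' `k * M` (electron-corrected, Da) and the ionization polarity.
#'
#' @return A data frame with columns `name`, `multiplier`, `mass_delta`,
#'   `polarity`.
#' @examples
#' adduct_table()
#' @export
adduct_table <- function() {
  data.frame(
    name = names(.ADDUCTS),
    multiplier = vapply(.ADDUCTS, `[[`, integer(1), "multiplier"),
    mass_delta = vapply(.ADDUCTS, `[[`, numeric(1), "mass_delta"),
    polarity = vapply(.ADDUCTS, `[[`, character(1), "polarity"),
    row.names = NULL
  )
}

#' Parse a molecular formula
#'
#' Parses a plain Hill-style formula string such as `"C4H4O4"` or — for
#' intrinsic (quaternary-nitrogen) cations — `"C14H22NO5+"` into element
#' counts and a net charge. The grammar is a sequence of element symbols each
#' followed by an optional count, with an optional trailing `+` or `-`
#' (unicode minus accepted). Parentheses, hydrates and isotope labels are not
#' supported. Element symbols are case-sensitive (`"CO"` is carbon monoxide,
#' `"Co"` is rejected as an unknown element).
#'
#' @param text formula string.
#' @return An object of class `mol_formula`: a list with `counts` (named
#'   integer vector of element counts) and `charge` (integer, -1/0/+1).
#' @examples
#' parse_formula("C4H4O4")      # maleic acid
#' parse_formula("C14H22NO4+")  # an intrinsic pyrrolidinium cation
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- gsub("[−]", "-", trimws(text))
  charge <- 0L
  if (grepl("[+-]$", x)) {
    charge <- if (endsWith(x, "+")) 1L else -1L
    x <- substr(x, 1L, nchar(x) - 1L)
  }
  if (nchar(x) == 0L && charge != 0L)
    stop("malformed formula '", text, "': charge sign without any element")
  counts <- integer(0)
  pos <- 1L
  n <- nchar(x)
  while (pos <= n) {
    rest <- substr(x, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[2]))
      stop("malformed formula '", text, "' at position ", pos,
           ": expected an element symbol")
    elt <- m[2]
    if (!elt %in% names(.MONOISOTOPIC_MASS))
      stop("unknown element symbol '", elt, "' in formula '", text,
           "' at position ", pos)
    cnt <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    if (cnt == 0L)
      stop("count of zero for element '", elt, "' in formula '", text,
           "' at position ", pos)
    counts[elt] <- (if (elt %in% names(counts)) counts[[elt]] else 0L) + cnt
    pos <- pos + nchar(m[1])
  }
  structure(list(counts = counts, charge = charge), class = "mol_formula")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula>", format_formula(x), "\n")
  invisible(x)
}

#' Render a molecular formula back to a string
#'
#' Inverse of [parse_formula()] up to element order (elements are emitted in
#' first-appearance order of the stored counts).
#'
#' @param formula a `mol_formula`.
#' @return A formula string.
#' @export
format_formula <- function(formula) {
  stopifnot(inherits(formula, "mol_formula"))
  body <- paste0(names(formula$counts),
                 ifelse(formula$counts == 1L, "", formula$counts),
                 collapse = "")
  paste0(body, if (formula$charge > 0L) "+" else if (formula$charge < 0L) "-")
}

#' Monoisotopic mass of a formula
#'
#' Sum of count times principal-isotope mass over all elements. The net charge
#' is ignored here; the electron correction is applied by [adduct_mz()]
#' through the adduct mass delta.
#'
#' @param formula a `mol_formula` (or a formula string, parsed on the fly).
#' @return Mass in Da. The empty formula has mass 0.
#' @examples
#' monoisotopic_mass("H2O")  # 18.0106
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "mol_formula"))
  if (length(formula$counts) == 0L) return(0)
  missing <- setdiff(names(formula$counts), names(.MONOISOTOPIC_MASS))
  if (length(missing))
    stop("no monoisotopic mass tabulated for element(s): ",
         paste(missing, collapse = ", "))
  sum(formula$counts * .MONOISOTOPIC_MASS[names(formula$counts)])
}

#' Calculated m/z of an ESI adduct ion
#'
#' `mz = k * M + delta` where `M` is the monoisotopic mass of the neutral (or
#' intrinsic-cation) formula and `k`, `delta` come from the adduct registry
#' ([adduct_table()]). Intrinsic cations (formulas with a trailing `+`) take
#' only the `"[M]+"` adduct; neutral formulas take any other adduct.
#'
#' @param formula a `mol_formula` or formula string.
#' @param adduct adduct label, e.g. `"[M+H]+"`, `"[M-H]-"`, `"[M+Na]+"`,
#'   `"[M+COOH]-"`, `"[2M-H]-"`, `"[M]+"`. Unicode minus signs are accepted.
#' @param digits decimals for display rounding (half-even); `NULL` for the
#'   unrounded value. Default 4, matching conventional reporting.
#' @return m/z in Da.
#' @examples
#' adduct_mz("C4H4O4", "[M-H]-")       # 115.0037, maleic acid
#' adduct_mz("C19H28NO5+", "[M]+")     # 350.1962, codonopyrrolidium A
#' @export
adduct_mz <- function(formula, adduct, digits = 4) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "mol_formula"))
  key <- normalize_adduct_name(adduct)
  spec <- .ADDUCTS[[key]]
  if (is.null(spec))
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(names(.ADDUCTS), collapse = ", "))
  if (formula$charge > 0L && key != "[M]+")
    stop("intrinsic cation formulas take only the [M]+ adduct, got '",
         adduct, "'")
  if (formula$charge == 0L && key == "[M]+")
    stop("the [M]+ adduct requires an intrinsic cation formula (trailing '+')")
  mz <- spec$multiplier * monoisotopic_mass(formula) + spec$mass_delta
  if (is.null(digits)) mz else round(mz, digits)
}

#' Parts-per-million mass error
#'
#' `1e6 * (detected - calculated) / calculated`.
#'
#' @param detected detected m/z (Da).
#' @param calculated calculated m/z (Da), must be positive.
#' @return ppm error (vectorized).
#' @examples
#' ppm_error(115.0045, 115.0037)
#' @export
ppm_error <- function(detected, calculated) {
  if (any(calculated <= 0))
    stop("calculated m/z must be positive")
  1e6 * (detected - calculated) / calculated
}

#' Annotate a peak list against a compound database
#'
#' Each peak is matched against every database record whose calculated adduct
#' m/z is within `ppm_tol` and whose retention time is within `rt_tol`; the
#' peak is annotated with the lowest-|ppm| candidate, ties broken by smallest
#' |delta RT| then lowest record id, so the output is deterministic.
#'
#' @param peaks data frame with columns `mz`, `rt_min` (and optionally
#'   `area`).
#' @param db compound database: data frame with columns `id`, `name`,
#'   `formula`, `adduct`, `rt_min`, `class` (see [read_compound_db()] /
#'   [cr_compounds()]).
#' @param ppm_tol mass tolerance in ppm (default 10).
#' @param rt_tol retention-time tolerance in minutes (default 0.20).
#' @param min_area optional area floor; peaks below it are not annotated
#'   (default `NULL`, off).
#' @return A data frame with one row per annotated peak: peak `mz`, `rt_min`,
#'   record `id`, `name`, `calculated_mz`, `error_ppm`, `delta_rt`.
#' @examples
#' db <- cr_compounds()
#' peaks <- data.frame(mz = db$detected_mz, rt_min = db$rt_min, area = 1)
#' nrow(match_peaks(peaks, db))  # 56
#' @export
match_peaks <- function(peaks, db, ppm_tol = 10, rt_tol = 0.20,
                        min_area = NULL) {
  stopifnot(ppm_tol > 0, rt_tol >= 0,
            all(c("mz", "rt_min") %in% names(peaks)))
  empty <- data.frame(mz = numeric(0), rt_min = numeric(0), id = integer(0),
                      name = character(0), calculated_mz = numeric(0),
                      error_ppm = numeric(0), delta_rt = numeric(0))
  if (nrow(peaks) == 0L || is.null(db) || nrow(db) == 0L) return(empty)
  calc <- vapply(seq_len(nrow(db)), function(i)
    adduct_mz(db$formula[i], db$adduct[i], digits = NULL), numeric(1))
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    if (!is.null(min_area) && "area" %in% names(peaks) &&
        peaks$area[i] < min_area) return(NULL)
    ppm <- ppm_error(peaks$mz[i], calc)
    drt <- peaks$rt_min[i] - db$rt_min
    ok <- abs(ppm) <= ppm_tol & abs(drt) <= rt_tol
    if (!any(ok)) return(NULL)
    cand <- which(ok)
    cand <- cand[order(abs(ppm[cand]), abs(drt[cand]), db$id[cand])]
    j <- cand[1L]
    data.frame(mz = peaks$mz[i], rt_min = peaks$rt_min[i], id = db$id[j],
               name = db$name[j], calculated_mz = calc[j],
               error_ppm = ppm[j], delta_rt = drt[j])
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# default neutral-loss catalog (Da)
.NEUTRAL_LOSSES <- c(glycosyl = 162.0528234, water = 18.0105646,
                     CO2 = 43.9898292)

#' Annotate a precursor/fragment pair with a neutral loss
#'
#' Returns the label of the catalog loss whose mass matches
#' `precursor_mz - fragment_mz` within `tol`, or `NA` if none does. The
#' default catalog holds the glycosyl (C6H10O5, 162.0528 Da), water and CO2
#' losses; ties go to the closest mass.
#'
#' @param precursor_mz precursor ion m/z (Da).
#' @param fragment_mz fragment ion m/z (Da); must be below the precursor.
#' @param losses named numeric vector of loss masses (Da).
#' @param tol absolute mass tolerance (Da), default 0.02.
#' @return Loss label (character) or `NA_character_`.
#' @examples
#' neutral_loss_annotate(581.2203, 419.1664)  # "glycosyl"
#' @export
neutral_loss_annotate <- function(precursor_mz, fragment_mz,
                                  losses = .NEUTRAL_LOSSES, tol = 0.02) {
  if (fragment_mz >= precursor_mz)
    stop("fragment m/z must be below precursor m/z")
  d <- abs((precursor_mz - fragment_mz) - losses)
  if (min(d) > tol) return(NA_character_)
  names(losses)[which.min(d)]
}

#' Read a compound database CSV
#'
#' Expects the header `id,name,formula,adduct,rt_min,class` (extra columns
#' are kept). Adduct labels may use ASCII or unicode minus. Each row's formula
#' and adduct are validated by parsing.
#'
#' @param path CSV path.
#' @return Data frame of compound records.
#' @export
read_compound_db <- function(path) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "name", "formula", "adduct", "rt_min", "class")
  miss <- setdiff(need, names(db))
  if (length(miss))
    stop("compound database is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(db$rt_min < 0)) stop("negative retention time in compound database")
  db$adduct <- normalize_adduct_name(db$adduct)
  for (i in seq_len(nrow(db))) parse_formula(db$formula[i])
  db
}

#' The 56-compound Codonopsis Radix reference database
#'
#' The identified-metabolite table shipped with the package: id, name,
#' molecular formula, adduct species, retention time, compound class
#' (Org/Alk/Ter/Lig/Pol/Oth = organic acids, alkaloids, terpenoids, lignans,
#' polyacetylenes, other), plus the published detected and calculated m/z for
#' verification.
#'
#' @return Data frame with 56 rows.
#' @examples
#' head(cr_compounds())
#' @export
cr_compounds <- function() {
  read_compound_db(system.file("extdata", "cr_compounds.csv",
                               package = "crorigin", mustWork = TRUE))
}
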