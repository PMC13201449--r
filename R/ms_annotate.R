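## Monoisotopic mass computation and ppm-tolerance peak annotation.
##
## Annotation is precursor-mass only: each observed m/z is compared against
## the [M+H]+ and [M-H]- adducts of every candidate formula, and matches
## within the ppm tolerance are reported.  MS/MS fragment columns are carried
## through untouched.

## Monoisotopic atomic masses (most abundant isotope), IUPAC/CODATA values
## to >= 7 decimals.  12C defines the scale.
.monoisotopic_masses <- c(
  C  = 12.0000000,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.9737616320,
  S  = 31.9720710015,
  Na = 22.9897692809,
  K  = 38.9637064864,
  Cl = 34.9688527100,
  F  = 18.9984031630,
  Br = 78.9183371000,
  I  = 126.9044719000,
  Si = 27.9769265325
)

## Proton mass with the electron correction (mass of H minus mass of an
## electron); the shift applied by protonation/deprotonation of an even-
## electron molecule.  Using the hydrogen *atom* mass here would miss the
## printed reference m/z values by ~2 ppm at m/z 300.
.proton_mass <- 1.00727646688

#' Supported ESI adducts
#'
#' @return A data.frame of the adduct specifications used by
#'   [annotate_peaks()]: label, signed mass shift (Da) and charge.
#'   `[M+H]+` shifts by `+1.00727646688` Da (proton mass, electron-corrected),
#'   `[M-H]-` by the negative; `M` is the neutral molecule.
#' @export
adduct_table <- function() {
  data.frame(label = c("[M+H]+", "[M-H]-", "M"),
             mass_shift = c(.proton_mass, -.proton_mass, 0),
             charge = c(1L, -1L, 0L),
             stringsAsFactors = FALSE)
}

#' Parse an elemental formula
#'
#' Hill-style formulas, e.g. `"C10H10O3"`. Underscore/subscript markup
#' (`"C_10_H_10_O_3_"`) is stripped before parsing. Counts are implicit 1 for
#' a bare symbol; explicit zero counts are rejected.
#'
#' @param text Formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C10H10O3")
#' parse_formula("CH4")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  clean <- gsub("[_₀-₉ ]", "", text)
  if (!nzchar(clean)) stop("empty formula string", call. = FALSE)
  counts <- integer(0)
  pos <- 1
  while (pos <= nchar(clean)) {
    rest <- substr(clean, pos, nchar(clean))
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0 || !nzchar(m[2])) {
      stop("malformed formula '", text, "' at position ", pos, call. = FALSE)
    }
    sym <- m[2]
    if (!sym %in% names(.monoisotopic_masses)) {
      stop("unknown element symbol '", sym, "' in '", text,
           "' at position ", pos, call. = FALSE)
    }
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    if (n < 1) {
      stop("zero count for element '", sym, "' in '", text, "'", call. = FALSE)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    pos <- pos + nchar(m[1])
  }
  counts
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the most-abundant-isotope atomic mass.
#'
#' @param formula Named integer vector from [parse_formula()], or a formula
#'   string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C10H10O3")  # 178.0629941
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(length(formula) >= 1, all(formula >= 1))
  unknown <- setdiff(names(formula), names(.monoisotopic_masses))
  if (length(unknown) > 0) {
    stop("element(s) missing from the mass table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(formula * .monoisotopic_masses[names(formula)])
}

#' Theoretical m/z of an adduct
#'
#' `(monoisotopic mass + mass shift) / |charge|`; the neutral species
#' (`"M"`, charge 0) is returned as its plain monoisotopic mass.
#'
#' @param formula Formula string or parsed vector.
#' @param adduct Adduct label, one of `adduct_table()$label`.
#' @return Theoretical m/z in Da.
#' @examples
#' adduct_mz("C10H10O3", "[M-H]-")  # 177.0557176
#' @export
adduct_mz <- function(formula, adduct = "[M-H]-") {
  tab <- adduct_table()
  row <- tab[tab$label == adduct, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown adduct label: ", adduct, call. = FALSE)
  m <- monoisotopic_mass(formula) + row$mass_shift
  if (row$charge == 0L) m else m / abs(row$charge)
}

#' Signed mass error in parts per million
#'
#' @param theoretical Theoretical mass (Da), `> 0`.
#' @param observed Observed mass (Da).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(theoretical, observed) {
  if (any(theoretical <= 0)) {
    stop("theoretical mass must be positive", call. = FALSE)
  }
  (observed - theoretical) / theoretical * 1e6
}

#' Annotate observed peaks against candidate formulas
#'
#' Every peak is compared with the protonated and deprotonated adducts of
#' every candidate; combinations within `tolerance_ppm` are reported, sorted
#' per peak by absolute ppm error. Peaks with no candidate in tolerance are
#' reported once with `matched = FALSE`. Adduct polarity is inferred by
#' trying both adducts, not read from metadata.
#'
#' @param peaks Data.frame with columns `mz` and optionally `rt_min` (and any
#'   fragment columns, carried through by peak index).
#' @param candidates Data.frame with columns `name` and `formula`.
#' @param tolerance_ppm Maximum absolute ppm error (default 5).
#' @param adducts Adduct labels to try (default `[M+H]+` and `[M-H]-`).
#' @return Data.frame with one row per reported (peak, candidate, adduct)
#'   combination: `peak`, `rt_min`, `mz`, `name`, `formula`, `adduct`,
#'   `theoretical_mz`, `ppm`, `matched`.
#' @export
annotate_peaks <- function(peaks, candidates, tolerance_ppm = 5,
                           adducts = c("[M+H]+", "[M-H]-")) {
  stopifnot(tolerance_ppm > 0, nrow(candidates) >= 1,
            all(c("name", "formula") %in% names(candidates)))
  if (!"mz" %in% names(peaks)) stop("peak table needs an 'mz' column",
                                    call. = FALSE)
  theo <- expand.grid(cand = seq_len(nrow(candidates)), adduct = adducts,
                      stringsAsFactors = FALSE)
  theo$mz <- mapply(function(ci, ad) adduct_mz(candidates$formula[ci], ad),
                    theo$cand, theo$adduct)
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    obs <- peaks$mz[i]
    rt <- if ("rt_min" %in% names(peaks)) peaks$rt_min[i] else NA_real_
    ppm <- ppm_error(theo$mz, obs)
    hit <- which(abs(ppm) <= tolerance_ppm)
    if (length(hit) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        peak = i, rt_min = rt, mz = obs, name = NA_character_,
        formula = NA_character_, adduct = NA_character_,
        theoretical_mz = NA_real_, ppm = NA_real_, matched = FALSE,
        stringsAsFactors = FALSE)
    } else {
      hit <- hit[order(abs(ppm[hit]))]
      rows[[length(rows) + 1]] <- data.frame(
        peak = i, rt_min = rt, mz = obs,
        name = candidates$name[theo$cand[hit]],
        formula = candidates$formula[theo$cand[hit]],
        adduct = theo$adduct[hit],
        theoretical_mz = theo$mz[hit], ppm = ppm[hit], matched = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
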