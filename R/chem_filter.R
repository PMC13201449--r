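## Drug-likeness rule filters and the BOILED-Egg GI-absorption classifier.
##
## The five rule sets (Lipinski, Ghose, Veber, Egan, Muegge) are kept in one
## table of bounds rather than scattered through code.  Every inequality that
## the original publications state as <= / >= is evaluated non-strictly, so a
## descriptor sitting exactly on a published bound does not violate; the two
## Muegge conditions published strictly (">4 carbons", ">1 heteroatom") stay
## strict.  A rule passes only with zero violations.

# One row per tested condition: rule, condition id, descriptor, bound, side.
# side "le": value <= bound passes; "ge": value >= bound passes;
# "gt": value > bound passes (strict, as published).
.dl_rule_table <- function() {
  df <- rbind(
    # Lipinski (Pfizer rule of five, MLOGP variant)
    data.frame(rule = "lipinski", condition = "mw_le_500",    descriptor = "mw",    bound = 500,   side = "le"),
    data.frame(rule = "lipinski", condition = "mlogp_le_4.15", descriptor = "mlogp", bound = 4.15, side = "le"),
    data.frame(rule = "lipinski", condition = "hba_le_10",    descriptor = "hba",   bound = 10,    side = "le"),
    data.frame(rule = "lipinski", condition = "hbd_le_5",     descriptor = "hbd",   bound = 5,     side = "le"),
    # Ghose
    data.frame(rule = "ghose", condition = "mw_ge_160",         descriptor = "mw",          bound = 160,  side = "ge"),
    data.frame(rule = "ghose", condition = "mw_le_480",         descriptor = "mw",          bound = 480,  side = "le"),
    data.frame(rule = "ghose", condition = "wlogp_ge_-0.4",     descriptor = "wlogp",       bound = -0.4, side = "ge"),
    data.frame(rule = "ghose", condition = "wlogp_le_5.6",      descriptor = "wlogp",       bound = 5.6,  side = "le"),
    data.frame(rule = "ghose", condition = "mr_ge_40",          descriptor = "mr",          bound = 40,   side = "ge"),
    data.frame(rule = "ghose", condition = "mr_le_130",         descriptor = "mr",          bound = 130,  side = "le"),
    data.frame(rule = "ghose", condition = "atoms_ge_20",       descriptor = "heavy_atoms", bound = 20,   side = "ge"),
    data.frame(rule = "ghose", condition = "atoms_le_70",       descriptor = "heavy_atoms", bound = 70,   side = "le"),
    # Veber
    data.frame(rule = "veber", condition = "rotb_le_10",  descriptor = "rotb", bound = 10,  side = "le"),
    data.frame(rule = "veber", condition = "tpsa_le_140", descriptor = "tpsa", bound = 140, side = "le"),
    # Egan
    data.frame(rule = "egan", condition = "wlogp_le_5.88",  descriptor = "wlogp", bound = 5.88,  side = "le"),
    data.frame(rule = "egan", condition = "tpsa_le_131.6",  descriptor = "tpsa",  bound = 131.6, side = "le"),
    # Muegge
    data.frame(rule = "muegge", condition = "mw_ge_200",        descriptor = "mw",          bound = 200, side = "ge"),
    data.frame(rule = "muegge", condition = "mw_le_600",        descriptor = "mw",          bound = 600, side = "le"),
    data.frame(rule = "muegge", condition = "xlogp_ge_-2",      descriptor = "xlogp",       bound = -2,  side = "ge"),
    data.frame(rule = "muegge", condition = "xlogp_le_5",       descriptor = "xlogp",       bound = 5,   side = "le"),
    data.frame(rule = "muegge", condition = "tpsa_le_150",      descriptor = "tpsa",        bound = 150, side = "le"),
    data.frame(rule = "muegge", condition = "rings_le_7",       descriptor = "rings",       bound = 7,   side = "le"),
    data.frame(rule = "muegge", condition = "carbons_gt_4",     descriptor = "carbons",     bound = 4,   side = "gt"),
    data.frame(rule = "muegge", condition = "heteroatoms_gt_1", descriptor = "heteroatoms", bound = 1,   side = "gt"),
    data.frame(rule = "muegge", condition = "rotb_le_15",       descriptor = "rotb",        bound = 15,  side = "le"),
    data.frame(rule = "muegge", condition = "hba_le_10",        descriptor = "hba",         bound = 10,  side = "le"),
    data.frame(rule = "muegge", condition = "hbd_le_5",         descriptor = "hbd",         bound = 5,   side = "le")
  )
  rownames(df) <- NULL
  df
}

#' Drug-likeness rule table
#'
#' The table of per-condition bounds behind the five drug-likeness filters
#' (Lipinski, Ghose, Veber, Egan, Muegge). One row per tested condition:
#' `rule`, `condition` (a stable identifier reported in violation lists),
#' `descriptor` (the [DescriptorSet][screen_compounds] field tested), `bound`
#' and `side` (`"le"`, `"ge"` non-strict; `"gt"` strict, as originally
#' published for Muegge's carbon and heteroatom minima).
#'
#' Each rule reads one logP variant: Lipinski the Moriguchi `mlogp`, Ghose and
#' Egan the atom-based `wlogp`, Muegge `xlogp`. This mapping is encoded in the
#' `descriptor` column and can be changed by passing an edited table to
#' [evaluate_rule()].
#'
#' @return A data.frame of rule conditions.
#' @export
dl_rules <- function() .dl_rule_table()

#' Evaluate one drug-likeness rule on a descriptor set
#'
#' @param rule_id One of `"lipinski"`, `"ghose"`, `"veber"`, `"egan"`,
#'   `"muegge"`.
#' @param descriptors A named list or one-row data.frame of molecular
#'   descriptors (fields as in the `descriptor` column of [dl_rules()]).
#' @param rules Rule table; defaults to [dl_rules()].
#' @return A list with `rule_id`, `violations` (character vector of violated
#'   condition ids) and `passed` (`TRUE` iff no violations).
#' @examples
#' evaluate_rule("lipinski", list(mw = 480, mlogp = 3.0, hbd = 2, hba = 8))
#' @export
evaluate_rule <- function(rule_id, descriptors, rules = dl_rules()) {
  if (!rule_id %in% unique(rules$rule)) {
    stop("unknown rule_id: ", rule_id, call. = FALSE)
  }
  descriptors <- as.list(descriptors)
  cond <- rules[rules$rule == rule_id, , drop = FALSE]
  needed <- unique(cond$descriptor)
  have <- vapply(needed, function(d) {
    !is.null(descriptors[[d]]) && !is.na(descriptors[[d]])
  }, logical(1))
  if (any(!have)) {
    stop("rule '", rule_id, "' requires missing descriptor(s): ",
         paste(needed[!have], collapse = ", "), call. = FALSE)
  }
  value <- vapply(cond$descriptor, function(d) as.numeric(descriptors[[d]]),
                  numeric(1))
  ok <- ifelse(cond$side == "le", value <= cond$bound,
        ifelse(cond$side == "ge", value >= cond$bound,
                                  value >  cond$bound))
  list(rule_id = rule_id,
       violations = cond$condition[!ok],
       passed = all(ok))
}

## BOILED-Egg HIA ("white") ellipse in (TPSA, WLOGP) space.
## Digitized parameters of the published gastrointestinal-absorption region:
## center (71.051, 2.292), full axes 142.081 x 8.740 (TPSA x WLOGP units),
## rotation -1.031425 degrees. Points on the boundary classify as high.
.boiled_egg_hia <- list(cx = 71.051, cy = 2.292,
                        a = 142.081 / 2, b = 8.740 / 2,
                        theta = -1.031425 * pi / 180)

#' Classify gastrointestinal absorption with the BOILED-Egg model
#'
#' Returns `"high"` iff the point (TPSA, WLOGP) lies inside or on the HIA
#' ("egg white") ellipse of the BOILED-Egg model. Only the HIA ellipse is
#' implemented; brain-penetration (yolk) classification is out of scope.
#'
#' @param tpsa Topological polar surface area (A^2), `>= 0`.
#' @param wlogp Atom-based logP.
#' @return `"high"` or `"low"` (vectorized).
#' @examples
#' classify_gi(30, 1.0)   # inside the absorption ellipse
#' classify_gi(200, 0.0)  # far outside
#' @export
classify_gi <- function(tpsa, wlogp) {
  stopifnot(all(is.finite(tpsa)), all(is.finite(wlogp)), all(tpsa >= 0))
  e <- .boiled_egg_hia
  dx <- tpsa - e$cx
  dy <- wlogp - e$cy
  xr <- cos(e$theta) * dx + sin(e$theta) * dy
  yr <- -sin(e$theta) * dx + cos(e$theta) * dy
  ifelse((xr / e$a)^2 + (yr / e$b)^2 <= 1, "high", "low")
}

#' Screen compounds by GI absorption and drug-likeness rule quorum
#'
#' Applies all five drug-likeness rules and the BOILED-Egg GI classifier to a
#' compound descriptor table. A compound is accepted iff its GI class is high
#' and at least `min_rules` of the five rules pass with zero violations.
#' Every compound carries all five verdicts regardless of acceptance, and
#' input order is preserved.
#'
#' @param descriptors A data.frame with one row per compound. Required
#'   columns: `compound_id`, plus every descriptor an enabled rule tests
#'   (`mw`, `wlogp`, `mlogp`, `xlogp`, `tpsa`, `hbd`, `hba`, `rotb`, `mr`,
#'   `heavy_atoms`, `carbons`, `heteroatoms`, `rings`). An optional `name`
#'   column is carried through.
#' @param min_rules Minimum number of fully-passed rules, in `0..5`
#'   (default 2).
#' @param rules Rule table; defaults to [dl_rules()].
#' @return A data.frame (screening report): one row per input compound with
#'   one logical column per rule, `n_rules_passed`, semicolon-joined
#'   `violations`, `gi_class` and `accepted`.
#' @export
screen_compounds <- function(descriptors, min_rules = 2, rules = dl_rules()) {
  stopifnot(length(min_rules) == 1, min_rules >= 0, min_rules <= 5)
  if (nrow(descriptors) == 0) {
    return(descriptors[0, "compound_id", drop = FALSE])
  }
  if (!"compound_id" %in% names(descriptors)) {
    stop("descriptor table needs a 'compound_id' column", call. = FALSE)
  }
  rule_ids <- unique(rules$rule)
  out <- data.frame(compound_id = descriptors$compound_id,
                    stringsAsFactors = FALSE)
  if ("name" %in% names(descriptors)) out$name <- descriptors$name
  verdicts <- matrix(NA, nrow(descriptors), length(rule_ids),
                     dimnames = list(NULL, rule_ids))
  viol <- character(nrow(descriptors))
  for (i in seq_len(nrow(descriptors))) {
    d <- as.list(descriptors[i, ])
    vv <- character(0)
    for (r in rule_ids) {
      v <- evaluate_rule(r, d, rules)
      verdicts[i, r] <- v$passed
      if (length(v$violations)) {
        vv <- c(vv, paste0(r, ":", v$violations))
      }
    }
    viol[i] <- paste(vv, collapse = ";")
  }
  for (r in rule_ids) out[[r]] <- as.logical(verdicts[, r])
  out$n_rules_passed <- rowSums(verdicts)
  out$violations <- viol
  out$gi_class <- classify_gi(descriptors$tpsa, descriptors$wlogp)
  out$accepted <- out$gi_class == "high" & out$n_rules_passed >= min_rules
  out
}

#' Accepted subset of a screening report
#'
#' @param report Output of [screen_compounds()].
#' @return The accepted rows, input order preserved.
#' @export
accepted_compounds <- function(report) {
  report[report$accepted, , drop = FALSE]
}
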