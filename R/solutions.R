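# Solution accounting: salt recipes -> per-ion totals, ionic strength, activities.

#' Table of ion species known to the package
#'
#' Charges are formal charges at physiological pH. Species modelled as neutral
#' (HEPES, glucose, sucrose, chelators, nucleotide complexes) carry charge 0 and
#' are excluded from ionic strength; their protonation states are pH-dependent
#' and are not modelled. The `permeant` flag marks ions a ligand-gated channel
#' could plausibly carry; bulky substitutes (NMDG+, gluconate-) and Mg2+ are
#' impermeant by default.
#'
#' @return data.frame with columns `ion`, `charge`, `permeant`.
#' @export
ion_table <- function() {
  data.frame(
    ion = c("Na", "K", "Ca", "Mg", "Cl", "NMDG", "gluconate",
            "HEPES", "glucose", "sucrose", "EGTA", "BAPTA",
            "MgATP", "NaGTP", "cGMP", "cAMP"),
    charge = c(1L, 1L, 2L, 2L, -1L, 1L, -1L,
               0L, 0L, 0L, 0L, 0L,
               0L, 0L, 0L, 0L),
    permeant = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

ion_charge <- function(ion) {
  tab <- ion_table()
  i <- match(ion, tab$ion)
  if (anyNA(i)) {
    stop("unknown ion species: ", paste(ion[is.na(i)], collapse = ", "),
         "; known species: ", paste(tab$ion, collapse = ", "))
  }
  tab$charge[i]
}

# Built-in salt stoichiometries (counts of each species per formula unit).
# Mg-ATP, Na-GTP, cGMP, cAMP, EGTA, BAPTA are modelled as single neutral
# species: their dissociation is pH-dependent and unstated, and they are
# excluded from ionic strength by design.
.salt_stoichiometries <- list(
  "NaCl"         = c(Na = 1, Cl = 1),
  "KCl"          = c(K = 1, Cl = 1),
  "CaCl2"        = c(Ca = 1, Cl = 2),
  "MgCl2"        = c(Mg = 1, Cl = 2),
  "NMDG-Cl"      = c(NMDG = 1, Cl = 1),
  "Na-gluconate" = c(Na = 1, gluconate = 1),
  "K-gluconate"  = c(K = 1, gluconate = 1),
  "HEPES"        = c(HEPES = 1),
  "glucose"      = c(glucose = 1),
  "sucrose"      = c(sucrose = 1),
  "EGTA"         = c(EGTA = 1),
  "BAPTA"        = c(BAPTA = 1),
  "Mg-ATP"       = c(MgATP = 1),
  "Na-GTP"       = c(NaGTP = 1),
  "cGMP"         = c(cGMP = 1),
  "cAMP"         = c(cAMP = 1)
)

#' Create a salt component of a solution recipe
#'
#' @param salt Name of the salt. Built-in stoichiometries cover the common
#'   electrophysiology salts (NaCl, KCl, CaCl2, MgCl2, NMDG-Cl, Na-gluconate,
#'   K-gluconate, ...); custom salts may supply `stoichiometry` explicitly.
#' @param mM Concentration in mM (non-negative).
#' @param stoichiometry Named integer vector, ion -> count per formula unit.
#'   The formula unit must be electroneutral.
#' @return An object of class `salt_component`.
#' @export
salt_component <- function(salt, mM, stoichiometry = NULL) {
  if (is.null(stoichiometry)) {
    stoichiometry <- .salt_stoichiometries[[salt]]
    if (is.null(stoichiometry)) {
      stop("no built-in stoichiometry for salt '", salt,
           "'; supply `stoichiometry` explicitly")
    }
  }
  if (!is.numeric(mM) || length(mM) != 1L || is.na(mM) || mM < 0) {
    stop("concentration of '", salt, "' must be a single non-negative number")
  }
  if (is.null(names(stoichiometry)) || any(stoichiometry <= 0) ||
      any(stoichiometry != round(stoichiometry))) {
    stop("stoichiometry of '", salt, "' must be named positive integer counts")
  }
  net <- sum(ion_charge(names(stoichiometry)) * stoichiometry)
  if (net != 0) {
    stop("salt '", salt, "' is not electroneutral: net formula-unit charge ",
         net)
  }
  structure(list(salt = salt, mM = mM, stoichiometry = stoichiometry),
            class = "salt_component")
}

#' Build a solution from salt components
#'
#' Per-ion totals are the stoichiometric sums concentration x count over all
#' components. pH titrants (e.g. NaOH) are not part of recipes by default; use
#' `titrant` to add an explicit ion amount when it is known.
#'
#' @param name Solution identifier.
#' @param side `"extracellular"` or `"intracellular"`.
#' @param components List of [salt_component()] objects.
#' @param titrant Optional named numeric vector of extra ion mM (e.g.
#'   `c(Na = 2)` for NaOH titration to pH).
#' @param osmolyte_note Free-text note, e.g. that osmolarity is balanced with
#'   sucrose in dilution series.
#' @return Object of class `ghk_solution` with an `ion_totals` field (named
#'   numeric, mM).
#' @export
build_solution <- function(name, side = c("extracellular", "intracellular"),
                           components = list(), titrant = NULL,
                           osmolyte_note = NULL) {
  side <- match.arg(side)
  stopifnot(is.list(components))
  totals <- numeric(0)
  for (comp in components) {
    if (!inherits(comp, "salt_component")) {
      stop("components must be salt_component objects (see salt_component())")
    }
    add <- comp$mM * comp$stoichiometry
    for (ion in names(add)) {
      totals[ion] <- (if (ion %in% names(totals)) totals[[ion]] else 0) +
        add[[ion]]
    }
  }
  if (!is.null(titrant)) {
    ion_charge(names(titrant))  # validate species
    for (ion in names(titrant)) {
      totals[ion] <- (if (ion %in% names(totals)) totals[[ion]] else 0) +
        titrant[[ion]]
    }
  }
  structure(
    list(name = name, side = side, components = components,
         ion_totals = totals, titrant = titrant,
         osmolyte_note = osmolyte_note),
    class = "ghk_solution"
  )
}

#' @export
print.ghk_solution <- function(x, ...) {
  cat("<ghk_solution> ", x$name, " (", x$side, ")\n", sep = "")
  cat("  components:",
      paste(sprintf("%g mM %s", vapply(x$components, `[[`, 0, "mM"),
                    vapply(x$components, `[[`, "", "salt")),
            collapse = ", "), "\n")
  tot <- x$ion_totals[x$ion_totals > 0]
  cat("  ion totals (mM):",
      paste(sprintf("%s=%g", names(tot), tot), collapse = ", "), "\n")
  if (!is.null(x$osmolyte_note)) cat("  note:", x$osmolyte_note, "\n")
  invisible(x)
}

#' Total concentration of one ion in a solution
#'
#' @param solution A `ghk_solution`.
#' @param ion Ion name. Ions absent from the recipe have total 0.
#' @return Concentration in mM.
#' @export
ion_total <- function(solution, ion) {
  stopifnot(inherits(solution, "ghk_solution"))
  ion_charge(ion)
  if (ion %in% names(solution$ion_totals)) solution$ion_totals[[ion]] else 0
}

#' Ionic strength of a solution
#'
#' I = 1/2 sum c_i z_i^2 over all charged species, including impermeant ones
#' (NMDG+, gluconate-, Mg2+). Neutral species do not contribute.
#'
#' @param solution A `ghk_solution`.
#' @return Ionic strength in mol/L.
#' @export
ionic_strength <- function(solution) {
  stopifnot(inherits(solution, "ghk_solution"))
  tot <- solution$ion_totals
  if (length(tot) == 0) return(0)
  z <- ion_charge(names(tot))
  0.5 * sum((tot / 1000) * z^2)
}

#' Activity-coefficient model
#'
#' `unity` takes activity = concentration (the conventional default for
#' permeability-ratio fits at these ionic strengths). `davies` applies the
#' Davies equation: log10(gamma) = -A z^2 (sqrt(I)/(1 + sqrt(I)) - linear * I).
#'
#' @param mode `"unity"` or `"davies"`.
#' @param A Debye-Huckel constant (per sqrt(M)); 0.509 at 25 C.
#' @param linear Davies linear coefficient (dimensionless), conventionally 0.3.
#' @return Object of class `activity_model`.
#' @export
activity_model <- function(mode = c("unity", "davies"), A = 0.509,
                           linear = 0.3) {
  mode <- match.arg(mode)
  structure(list(mode = mode, A = A, linear = linear),
            class = "activity_model")
}

#' Davies activity coefficient
#'
#' @param z Ion charge.
#' @param I Ionic strength in mol/L.
#' @param model An `activity_model` (its `A` and `linear` are used).
#' @return Dimensionless coefficient in (0, 1].
#' @export
davies_gamma <- function(z, I, model = activity_model("davies")) {
  if (I < 0) stop("ionic strength must be non-negative")
  sqI <- sqrt(I)
  10^(-model$A * z^2 * (sqI / (1 + sqI) - model$linear * I))
}

#' Ion activity in a solution
#'
#' @param solution A `ghk_solution`.
#' @param ion Ion name; must be present in the solution's totals.
#' @param model An [activity_model()].
#' @return Activity in mM.
#' @export
ion_activity <- function(solution, ion, model = activity_model("unity")) {
  stopifnot(inherits(solution, "ghk_solution"),
            inherits(model, "activity_model"))
  if (!(ion %in% names(solution$ion_totals))) {
    stop("ion '", ion, "' not present in solution '", solution$name, "'")
  }
  conc <- solution$ion_totals[[ion]]
  if (model$mode == "unity") return(conc)
  z <- ion_charge(ion)
  conc * davies_gamma(z, ionic_strength(solution), model)
}

#' Dilution series over the NaCl component
#'
#' Scales the NaCl component of `base` by each factor, leaving other components
#' unchanged; osmolarity is understood to be balanced with sucrose (recorded as
#' a note, not as ions).
#'
#' @param base A `ghk_solution` containing an NaCl component.
#' @param factors Dilution fractions in (0, 1].
#' @return List of `ghk_solution`, one per factor, named e.g. `"0.5NaCl"`.
#' @export
dilution_series <- function(base, factors) {
  stopifnot(inherits(base, "ghk_solution"))
  salts <- vapply(base$components, `[[`, "", "salt")
  if (!("NaCl" %in% salts)) stop("base solution has no NaCl component")
  if (any(factors <= 0 | factors > 1)) {
    stop("dilution factors must lie in (0, 1]")
  }
  out <- lapply(factors, function(f) {
    comps <- lapply(base$components, function(cmp) {
      if (cmp$salt == "NaCl") salt_component("NaCl", cmp$mM * f) else cmp
    })
    build_solution(
      name = paste0(format(f), "NaCl"), side = base$side, components = comps,
      titrant = base$titrant,
      osmolyte_note = if (f < 1) "osmolarity balanced with sucrose" else NULL
    )
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Registry of built-in solutions
#'
#' The recording solutions used throughout the analysis:
#' \describe{
#'   \item{I1}{K-rich intracellular for I-V experiments: 115 K-gluconate,
#'     25 KCl, 0.5 CaCl2, 50 HEPES, 5 Mg-ATP, 0.5 Na-GTP, 0.5 cGMP, 0.5 cAMP,
#'     1 BAPTA (mM).}
#'   \item{I2}{NaCl intracellular for dilution-potential experiments: 145 NaCl,
#'     1 CaCl2, 1 MgCl2, 1 EGTA, 10 HEPES, 10 glucose.}
#'   \item{ES1}{Standard external: 150 NaCl, 5 KCl, 1 CaCl2, 4 MgCl2,
#'     15 HEPES, 10 glucose (Cl- total 165 mM).}
#'   \item{ES2}{Low Na+: as ES1 except 15 NaCl + 135 NMDG-Cl.}
#'   \item{ES3_recipe}{Low Cl- as per the printed recipe: as ES1 except
#'     30 NaCl + 120 Na-gluconate (Cl- total 45 mM).}
#'   \item{ES3_legend}{Low Cl- variant matching the printed summary
#'     (150 mM Na+, 30 mM Cl-): 15 NaCl + 135 Na-gluconate, otherwise as ES1.}
#'   \item{ES4}{High K+: as ES2 except 140 KCl, 0 NMDG-Cl.}
#'   \item{ES5}{High Ca2+: as ES2 except 25 CaCl2, 85 NMDG-Cl.}
#'   \item{1NaCl, 0.5NaCl, 0.25NaCl}{Dilution-potential externals: 145 / 72.5 /
#'     36.25 mM NaCl with 1 CaCl2, 1 MgCl2, 10 HEPES; dilutions balanced with
#'     sucrose.}
#' }
#'
#' Two ES3 variants are shipped because the printed recipe and the printed
#' ionic summary disagree (45 vs 30 mM Cl-); no attempt is made to decide
#' which was used.
#'
#' @return Named list of `ghk_solution` objects.
#' @export
solution_registry <- function() {
  es1 <- function(name, nacl = 150, extra = list()) {
    comps <- c(list(salt_component("NaCl", nacl)), extra,
               list(salt_component("KCl", 5), salt_component("CaCl2", 1),
                    salt_component("MgCl2", 4), salt_component("HEPES", 15),
                    salt_component("glucose", 10)))
    build_solution(name, "extracellular", comps)
  }
  reg <- list(
    I1 = build_solution("I1", "intracellular", list(
      salt_component("K-gluconate", 115), salt_component("KCl", 25),
      salt_component("CaCl2", 0.5), salt_component("HEPES", 50),
      salt_component("Mg-ATP", 5), salt_component("Na-GTP", 0.5),
      salt_component("cGMP", 0.5), salt_component("cAMP", 0.5),
      salt_component("BAPTA", 1))),
    I2 = build_solution("I2", "intracellular", list(
      salt_component("NaCl", 145), salt_component("CaCl2", 1),
      salt_component("MgCl2", 1), salt_component("EGTA", 1),
      salt_component("HEPES", 10), salt_component("glucose", 10))),
    ES1 = es1("ES1"),
    ES2 = es1("ES2", nacl = 15,
              extra = list(salt_component("NMDG-Cl", 135))),
    ES3_recipe = es1("ES3_recipe", nacl = 30,
                     extra = list(salt_component("Na-gluconate", 120))),
    ES3_legend = es1("ES3_legend", nacl = 15,
                     extra = list(salt_component("Na-gluconate", 135)))
  )
  # ES4/ES5 derive from ES2 with stated substitutions
  reg$ES4 <- build_solution("ES4", "extracellular", list(
    salt_component("NaCl", 15), salt_component("KCl", 140),
    salt_component("CaCl2", 1), salt_component("MgCl2", 4),
    salt_component("HEPES", 15), salt_component("glucose", 10)))
  reg$ES5 <- build_solution("ES5", "extracellular", list(
    salt_component("NaCl", 15), salt_component("NMDG-Cl", 85),
    salt_component("KCl", 5), salt_component("CaCl2", 25),
    salt_component("MgCl2", 4), salt_component("HEPES", 15),
    salt_component("glucose", 10)))
  base_ext <- build_solution("1NaCl", "extracellular", list(
    salt_component("NaCl", 145), salt_component("CaCl2", 1),
    salt_component("MgCl2", 1), salt_component("HEPES", 10)))
  dil <- dilution_series(base_ext, c(1, 0.5, 0.25))
  reg[names(dil)] <- dil
  reg
}

#' Fetch a built-in solution by name
#'
#' @param name Registry name (see [solution_registry()]).
#' @return A `ghk_solution`.
#' @export
get_solution <- function(name) {
  reg <- solution_registry()
  if (!(name %in% names(reg))) {
    stop("unknown solution '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}

#' Write solutions to a YAML config
#'
#' @param solutions Named list of `ghk_solution`.
#' @param path Output file path.
#' @export
solutions_to_yaml <- function(solutions, path) {
  doc <- lapply(solutions, function(s) {
    list(name = s$name, side = s$side,
         components = lapply(s$components, function(cmp) {
           list(salt = cmp$salt, mM = cmp$mM,
                stoichiometry = as.list(cmp$stoichiometry))
         }))
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read solutions from a YAML config
#'
#' @param path File written by [solutions_to_yaml()] or hand-edited in the same
#'   layout.
#' @return Named list of `ghk_solution`.
#' @export
solutions_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- lapply(doc, function(s) {
    comps <- lapply(s$components, function(cmp) {
      salt_component(cmp$salt, cmp$mM,
                     stoichiometry = unlist(cmp$stoichiometry))
    })
    build_solution(s$name, s$side, comps)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
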