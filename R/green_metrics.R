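.spec_error <- function(msg) {
  stop(structure(class = c("fluorsense_spec_error", "fluorsense_input_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Describe one chemical species of a reaction
#'
#' @param name Species name (free text).
#' @param formula Molecular formula (string or `chem_formula`); required
#'   for reactants, optional for auxiliaries such as solvents.
#' @param equivalents Stoichiometric coefficient (> 0); the product is
#'   taken as 1 equivalent.
#' @param mass_used Mass actually charged, in grams (optional).
#' @param role One of `"reactant"`, `"catalyst"`, `"solvent"`, `"workup"`.
#' @return A `species_input` list.
#' @export
species <- function(name, formula = NULL, equivalents = 1, mass_used = NULL,
                    role = c("reactant", "catalyst", "solvent", "workup")) {
  role <- match.arg(role)
  if (!is.null(formula)) formula <- as_formula(formula)
  if (!is.numeric(equivalents) || length(equivalents) != 1L || equivalents <= 0)
    .spec_error("equivalents must be a single positive number")
  if (!is.null(mass_used) &&
      (!is.numeric(mass_used) || length(mass_used) != 1L || mass_used < 0))
    .spec_error("mass_used must be a single non-negative number of grams")
  if (role == "reactant" && is.null(formula))
    .spec_error(sprintf("reactant '%s' must carry a molecular formula", name))
  structure(list(name = name, formula = formula, equivalents = equivalents,
                 mass_used = mass_used, role = role),
            class = "species_input")
}

#' Stoichiometric reaction specification
#'
#' Bundles reactants, auxiliaries (catalyst / solvent / workup), the
#' product and optional byproducts for green-metrics computation. The
#' product coefficient is 1; reactant `equivalents` are relative to it.
#'
#' @param reactants List of [species()] with role `"reactant"`.
#' @param product_formula Product formula (string or `chem_formula`).
#' @param auxiliaries Optional list of [species()] with non-reactant roles.
#' @param product_mass Isolated product mass in grams (optional).
#' @param byproduct_formulas Optional list of formulas for stoichiometric
#'   byproducts (e.g. condensation water). When omitted, water is inferred
#'   from the element balance where possible.
#' @return A `reaction_spec` object.
#' @export
reaction_spec <- function(reactants, product_formula, auxiliaries = list(),
                          product_mass = NULL, byproduct_formulas = NULL) {
  if (length(reactants) == 0L) .spec_error("at least one reactant is required")
  if (inherits(reactants, "species_input")) reactants <- list(reactants)
  if (inherits(auxiliaries, "species_input")) auxiliaries <- list(auxiliaries)
  for (r in reactants) {
    if (!inherits(r, "species_input")) .spec_error("reactants must be species() objects")
    if (r$role != "reactant") .spec_error("all entries in 'reactants' must have role 'reactant'")
  }
  for (a in auxiliaries) {
    if (!inherits(a, "species_input")) .spec_error("auxiliaries must be species() objects")
    if (a$role == "reactant") .spec_error("auxiliaries may not have role 'reactant'")
  }
  if (!is.null(byproduct_formulas))
    byproduct_formulas <- lapply(byproduct_formulas, as_formula)
  structure(list(reactants = reactants,
                 auxiliaries = auxiliaries,
                 product_formula = as_formula(product_formula),
                 product_mass = product_mass,
                 byproduct_formulas = byproduct_formulas),
            class = "reaction_spec")
}

.species_moles <- function(sp, masses) {
  if (is.null(sp$mass_used) || is.null(sp$formula)) return(NA_real_)
  sp$mass_used / molecular_weight(sp$formula, masses)
}

# Limiting reactant by smallest moles/equivalents; NA when masses missing.
.theoretical_product_moles <- function(spec, masses) {
  ratios <- vapply(spec$reactants, function(r) {
    mol <- .species_moles(r, masses)
    mol / r$equivalents
  }, numeric(1))
  if (anyNA(ratios)) return(NA_real_)
  min(ratios)
}

#' Atom economy
#'
#' AE = 100 * MW(product) / sum_i nu_i * MW(reactant_i). Independent of
#' masses charged and of yield; a pure property of the balanced equation.
#'
#' @param spec A [reaction_spec()].
#' @param masses Mass table; defaults to [atomic_masses()].
#' @return Atom economy in percent.
#' @examples
#' rx <- reaction_spec(
#'   reactants = list(species("aminobenzophenone", "C13H11NO", equivalents = 2),
#'                    species("dione", "C12H18O2", equivalents = 1)),
#'   product_formula = "C38H32N2")
#' atom_economy(rx)
#' @export
atom_economy <- function(spec, masses = atomic_masses()) {
  mw_in <- vapply(spec$reactants, function(r) {
    if (is.null(r$formula)) .spec_error(sprintf("reactant '%s' lacks a formula", r$name))
    r$equivalents * molecular_weight(r$formula, masses)
  }, numeric(1))
  100 * molecular_weight(spec$product_formula, masses) / sum(mw_in)
}

#' Percent yield from the limiting reactant
#'
#' @inheritParams atom_economy
#' @return Percent yield, or `NA` when product mass or reactant masses are
#'   unavailable.
#' @export
percent_yield <- function(spec, masses = atomic_masses()) {
  if (is.null(spec$product_mass)) return(NA_real_)
  theo <- .theoretical_product_moles(spec, masses)
  if (is.na(theo)) return(NA_real_)
  obtained <- spec$product_mass / molecular_weight(spec$product_formula, masses)
  100 * obtained / theo
}

#' Reaction mass efficiency
#'
#' RME = 100 * product mass / total reactant mass.
#'
#' @inheritParams atom_economy
#' @return RME in percent.
#' @export
reaction_mass_efficiency <- function(spec) {
  if (is.null(spec$product_mass)) .spec_error("product mass required for RME")
  m_in <- vapply(spec$reactants, function(r) {
    if (is.null(r$mass_used)) .spec_error(sprintf("reactant '%s' lacks a mass", r$name))
    r$mass_used
  }, numeric(1))
  100 * spec$product_mass / sum(m_in)
}

#' Carbon efficiency
#'
#' CE = 100 * (moles product * product C count) /
#' sum_i (moles reactant_i * C count_i), with moles taken from the masses
#' actually charged, so CE scales linearly with yield.
#'
#' @inheritParams atom_economy
#' @return CE in percent.
#' @export
carbon_efficiency <- function(spec, masses = atomic_masses()) {
  if (is.null(spec$product_mass)) .spec_error("product mass required for CE")
  c_in <- vapply(spec$reactants, function(r) {
    mol <- .species_moles(r, masses)
    if (is.na(mol)) .spec_error(sprintf("reactant '%s' lacks a mass", r$name))
    mol * carbon_count(r$formula)
  }, numeric(1))
  if (sum(c_in) <= 0) .spec_error("carbon efficiency undefined: no reactant carbon")
  mol_p <- spec$product_mass / molecular_weight(spec$product_formula, masses)
  100 * mol_p * carbon_count(spec$product_formula) / sum(c_in)
}

#' Process mass intensity
#'
#' PMI = total mass of included inputs / product mass. By default the
#' basis counts reactants and catalyst but excludes solvent: recyclable
#' reaction media (e.g. deep eutectic solvents) are conventionally left
#' out of the intensity when they are recovered and reused.
#'
#' @inheritParams atom_economy
#' @param include_roles Character vector of roles counted as input mass.
#' @return PMI (dimensionless, >= 1 for a mass-balanced process).
#' @export
process_mass_intensity <- function(spec,
                                   include_roles = c("reactant", "catalyst")) {
  if (is.null(spec$product_mass) || spec$product_mass <= 0)
    .spec_error("positive product mass required for PMI")
  all_species <- c(spec$reactants, spec$auxiliaries)
  included <- Filter(function(s) s$role %in% include_roles, all_species)
  m_in <- vapply(included, function(s) {
    if (is.null(s$mass_used))
      .spec_error(sprintf("species '%s' (role %s) lacks a mass", s$name, s$role))
    s$mass_used
  }, numeric(1))
  sum(m_in) / spec$product_mass
}

#' E-factor (waste mass per product mass)
#'
#' Computed on the same input basis as [process_mass_intensity()], so
#' E-factor = PMI - 1 holds identically.
#'
#' @inheritParams process_mass_intensity
#' @return E-factor (dimensionless, >= 0).
#' @export
e_factor <- function(spec, include_roles = c("reactant", "catalyst")) {
  process_mass_intensity(spec, include_roles) - 1
}

#' Element-balance audit
#'
#' Checks that summed reactant elements (weighted by equivalents) equal
#' product plus byproduct elements. When byproducts are not given, the
#' difference is tested for being an integer number of water molecules
#' (the implicit byproduct of condensation reactions) and reported.
#'
#' @inheritParams atom_economy
#' @return List with `balanced` (logical), `difference` (named integer
#'   vector of unaccounted elements, reactants minus products) and
#'   `inferred_water` (integer count or `NA`).
#' @export
element_balance <- function(spec) {
  add_counts <- function(acc, counts, mult = 1) {
    for (el in names(counts)) {
      acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0) + mult * counts[[el]]
    }
    acc
  }
  lhs <- numeric(0)
  for (r in spec$reactants) lhs <- add_counts(lhs, r$formula$counts, r$equivalents)
  rhs <- add_counts(numeric(0), spec$product_formula$counts)
  for (b in spec$byproduct_formulas %||% list()) rhs <- add_counts(rhs, b$counts)
  els <- union(names(lhs), names(rhs))
  diffv <- setNames(vapply(els, function(e) {
    (if (e %in% names(lhs)) lhs[[e]] else 0) - (if (e %in% names(rhs)) rhs[[e]] else 0)
  }, numeric(1)), els)
  diffv <- diffv[diffv != 0]
  inferred <- NA_integer_
  balanced <- length(diffv) == 0L
  if (!balanced && is.null(spec$byproduct_formulas) &&
      setequal(names(diffv), c("H", "O")) &&
      diffv[["H"]] > 0 && diffv[["O"]] > 0 &&
      diffv[["H"]] == 2 * diffv[["O"]] &&
      diffv[["O"]] == round(diffv[["O"]])) {
    inferred <- as.integer(diffv[["O"]])
    balanced <- TRUE
    diffv <- numeric(0)
  }
  list(balanced = balanced, difference = diffv, inferred_water = inferred)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full green-metrics report
#'
#' Computes every metric that the specification allows and flags the rest
#' as unavailable (with the reason), never silently zero. The report also
#' carries the element-balance audit and, when masses permit, the percent
#' yield. `ce_stoichiometric` is the theoretical-basis carbon efficiency
#' (product carbon over reactant carbon for the balanced equation at full
#' conversion), reported alongside the yield-dependent `CE`.
#'
#' @inheritParams process_mass_intensity
#' @param masses Mass table; defaults to [atomic_masses()].
#' @return An object of class `green_report`.
#' @export
green_report <- function(spec, masses = atomic_masses(),
                         include_roles = c("reactant", "catalyst")) {
  try_metric <- function(expr) {
    tryCatch(list(value = expr, reason = NA_character_),
             error = function(e) list(value = NA_real_, reason = conditionMessage(e)))
  }
  ae <- try_metric(atom_economy(spec, masses))
  pmi <- try_metric(process_mass_intensity(spec, include_roles))
  ef <- if (is.na(pmi$value)) pmi else list(value = pmi$value - 1, reason = NA_character_)
  ce <- try_metric(carbon_efficiency(spec, masses))
  rme <- try_metric(reaction_mass_efficiency(spec))
  yld <- try_metric(percent_yield(spec, masses))
  c_in_stoich <- sum(vapply(spec$reactants,
                            function(r) r$equivalents * carbon_count(r$formula),
                            numeric(1)))
  ce_stoich <- if (c_in_stoich > 0)
    100 * carbon_count(spec$product_formula) / c_in_stoich else NA_real_
  structure(list(AE = ae$value, PMI = pmi$value, CE = ce$value,
                 RME = rme$value, E_factor = ef$value,
                 yield_pct = yld$value,
                 ce_stoichiometric = ce_stoich,
                 balance = element_balance(spec),
                 unavailable = Filter(Negate(is.na),
                                      c(AE = ae$reason, PMI = pmi$reason,
                                        CE = ce$reason, RME = rme$reason,
                                        yield_pct = yld$reason)),
                 include_roles = include_roles),
            class = "green_report")
}

#' @export
print.green_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "   --" else sprintf("%6.1f", v)
  cat("Green-metrics report\n")
  cat(sprintf("  AE       %s %%\n", fmt(x$AE)))
  cat(sprintf("  PMI      %s\n", fmt(x$PMI)))
  cat(sprintf("  CE       %s %%\n", fmt(x$CE)))
  cat(sprintf("  RME      %s %%\n", fmt(x$RME)))
  cat(sprintf("  E-factor %s\n", if (is.na(x$E_factor)) "   --" else sprintf("%6.3f", x$E_factor)))
  cat(sprintf("  Yield    %s %%\n", fmt(x$yield_pct)))
  bal <- x$balance
  cat(sprintf("  Element balance: %s%s\n",
              if (bal$balanced) "OK" else "UNBALANCED",
              if (!is.na(bal$inferred_water))
                sprintf(" (inferred %d H2O byproduct%s)", bal$inferred_water,
                        if (bal$inferred_water == 1) "" else "s") else ""))
  if (length(x$unavailable) > 0)
    cat("  Unavailable:", paste(names(x$unavailable), collapse = ", "), "\n")
  invisible(x)
}

#' Read a reaction specification from YAML or JSON
#'
#' Schema: top-level keys `reactants` (list of `{name, formula,
#' equivalents, mass_g}`), optional `auxiliaries` (adds `role`), `product`
#' (`{name, formula, mass_g}`), optional `byproducts` (list of formula
#' strings).
#'
#' @param path File path; format chosen by extension (.yaml/.yml vs .json).
#' @return A [reaction_spec()].
#' @export
read_reaction_spec <- function(path) {
  if (!file.exists(path)) .spec_error(sprintf("reaction file not found: %s", path))
  raw <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) .spec_error(sprintf("cannot parse %s: %s", path,
                                            conditionMessage(e))))
  if (is.null(raw$reactants) || is.null(raw$product))
    .spec_error("reaction file must define 'reactants' and 'product'")
  mk <- function(entry, default_role = "reactant") {
    species(name = entry$name %||% "unnamed",
            formula = entry$formula,
            equivalents = entry$equivalents %||% 1,
            mass_used = entry$mass_g,
            role = entry$role %||% default_role)
  }
  reaction_spec(
    reactants = lapply(raw$reactants, mk),
    auxiliaries = lapply(raw$auxiliaries %||% list(), mk, default_role = "solvent"),
    product_formula = raw$product$formula,
    product_mass = raw$product$mass_g,
    byproduct_formulas = if (!is.null(raw$byproducts)) as.list(raw$byproducts))
}
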