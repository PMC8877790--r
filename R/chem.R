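# Standard atomic weights (IUPAC 2021, conventional values) for the
# elements appearing in small organic toxicants.
ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098, Br = 79.904,
  I = 126.904
)

#' Molar mass from a molecular formula
#'
#' Parses a simple Hill-style formula (element symbols with optional
#' counts, no parentheses or charges) and sums standard atomic weights.
#'
#' @param formula Character, e.g. `"C13H9Cl3N2O"`.
#' @return Molar mass in g/mol.
#' @export
#' @examples
#' molar_mass_from_formula("C13H9Cl3N2O") # triclocarban, ~315.58
molar_mass_from_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (paste(tokens, collapse = "") != formula) {
    stop(sprintf("cannot parse molecular formula '%s'", formula), call. = FALSE)
  }
  mass <- 0
  for (tok in tokens) {
    el <- gsub("[0-9]", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.numeric(n) else 1
    if (!el %in% names(ATOMIC_WEIGHTS)) {
      stop(sprintf("unknown element '%s' in formula '%s'", el, formula), call. = FALSE)
    }
    mass <- mass + ATOMIC_WEIGHTS[[el]] * n
  }
  mass
}

#' Registry of study chemicals
#'
#' Identity and molar mass for the three endocrine-disrupting chemicals
#' under study. Molar masses are computed from the molecular formulas
#' with standard atomic weights (and validated against them in the test
#' suite), because published exposure tables print converted
#' concentrations but not the masses used.
#'
#' @param extra Optional tibble (or path to a TSV) with columns `name`,
#'   `cas`, `formula` to extend the registry; molar masses are computed
#'   from the formulas.
#' @return Tibble with `name`, `cas`, `formula`, `molar_mass` (g/mol).
#' @export
chemical_registry <- function(extra = NULL) {
  base <- tibble::tibble(
    name = c("triclosan", "triclocarban", "4-nonylphenol"),
    cas = c("3380-34-5", "101-20-2", "104-40-5"),
    formula = c("C12H7Cl3O2", "C13H9Cl3N2O", "C15H24O")
  )
  if (!is.null(extra)) {
    if (is.character(extra) && length(extra) == 1L) {
      extra <- readr::read_tsv(extra, show_col_types = FALSE)
    }
    stopifnot(all(c("name", "cas", "formula") %in% names(extra)))
    base <- dplyr::bind_rows(base, extra[, c("name", "cas", "formula")])
  }
  base$molar_mass <- unname(vapply(base$formula, molar_mass_from_formula, numeric(1)))
  base
}

lookup_chemical <- function(chemical, registry = chemical_registry()) {
  if (is.numeric(chemical)) {
    stopifnot(chemical > 0)
    return(list(name = "custom", molar_mass = chemical))
  }
  hit <- registry[registry$name == chemical, ]
  if (nrow(hit) != 1L) {
    stop(sprintf(
      "chemical '%s' not in registry (known: %s)",
      chemical, paste(registry$name, collapse = ", ")
    ), call. = FALSE)
  }
  list(name = hit$name, molar_mass = hit$molar_mass)
}

#' Convert a molar concentration to a mass concentration
#'
#' ug/L = nmol/L x molar mass (g/mol) x 1e-3. The inverse,
#' [ugL_to_nM()], round-trips to machine precision.
#'
#' @param chemical A registry chemical name, or a molar mass (g/mol).
#' @param nM Concentration in nmol/L (>= 0).
#' @param registry Chemical registry, see [chemical_registry()].
#' @return Concentration in ug/L (full precision; round to 1 decimal
#'   for display).
#' @export
#' @examples
#' round(nM_to_ugL("triclocarban", 10), 1) # 3.2
nM_to_ugL <- function(chemical, nM, registry = chemical_registry()) {
  if (any(nM < 0)) stop("concentration must be non-negative", call. = FALSE)
  chem <- lookup_chemical(chemical, registry)
  nM * chem$molar_mass * 1e-3
}

#' @rdname nM_to_ugL
#' @param ugL Concentration in ug/L (>= 0).
#' @export
ugL_to_nM <- function(chemical, ugL, registry = chemical_registry()) {
  if (any(ugL < 0)) stop("concentration must be non-negative", call. = FALSE)
  chem <- lookup_chemical(chemical, registry)
  ugL / (chem$molar_mass * 1e-3)
}

#' Exposure design for the three-chemical study
#'
#' The nominal design: five concentrations per chemical (0.1–1000 nM
#' for triclosan and 4-nonylphenol, 0.01–100 nM for triclocarban), each
#' at two exposure durations — 120 h (4 hpf to 5 dpf, "long-term") and
#' 24 h (4–5 dpf, "short-term") — plus a vehicle control per chemical
#' and duration (concentration 0).
#'
#' @param include_controls Add the concentration-0 vehicle rows.
#' @return Tibble with `chemical`, `concentration_nM`, `duration`.
#' @export
study_design <- function(include_controls = TRUE) {
  concs <- list(
    "triclosan" = c(0.1, 1, 10, 100, 1000),
    "triclocarban" = c(0.01, 0.1, 1, 10, 100),
    "4-nonylphenol" = c(0.1, 1, 10, 100, 1000)
  )
  out <- purrr::map_dfr(names(concs), function(ch) {
    cc <- concs[[ch]]
    if (include_controls) cc <- c(0, cc)
    tidyr::expand_grid(
      chemical = ch, concentration_nM = cc,
      duration = c("24h", "120h")
    )
  })
  dplyr::arrange(out, .data$chemical, .data$duration, .data$concentration_nM)
}

#' Check observed condition labels against a design
#'
#' Flags design concentrations that were never observed and observed
#' labels absent from the design — useful for catching internal
#' inconsistencies between a stated design and the condition columns of
#' a reported table.
#'
#' @param design_concs Numeric vector of designed concentrations (nM).
#' @param observed_concs Numeric vector of observed condition labels.
#' @return A tibble with `concentration_nM` and `status`
#'   (`"ok"`, `"design_unobserved"`, `"observed_unknown"`).
#' @export
#' @examples
#' validate_design(c(0.01, 0.1, 1, 10, 100), c(0.01, 1, 100))
validate_design <- function(design_concs, observed_concs) {
  all_c <- sort(unique(c(design_concs, observed_concs)))
  tibble::tibble(
    concentration_nM = all_c,
    status = dplyr::case_when(
      all_c %in% design_concs & all_c %in% observed_concs ~ "ok",
      all_c %in% design_concs ~ "design_unobserved",
      TRUE ~ "observed_unknown"
    )
  )
}
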