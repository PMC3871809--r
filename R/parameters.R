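#' Parameter registry for the kiwifruit berry model
#'
#' Returns the full registry of model constants: one row per parameter with
#' its group, default value, admissible range, unit, and a short
#' description. The defaults are the base parameterization of the model
#' (initial state, osmotic baselines, cell-expansion schedule, active
#' uptake, composite-membrane properties, skin permeance, pedicel
#' conductance shapes, starch sub-model, respiration, physical constants,
#' and the fruit surface-area allometry).
#'
#' Three cell-expansion constants are printed in two conflicting forms in
#' the model's source description (running text vs parameter table). The
#' defaults here are the dynamically consistent combination: `Y` = 2 bar
#' (the value justified against turgor measurements), with
#' `phi_2` = 0.000135 bar^-1 h^-1 and `phi_k` = 0.028 d^-1 (the
#' tabulated values -- the only combination under which late-season
#' turgor rises to the reported ~15 bar while fresh-weight growth slows,
#' rather than water uptake running away). The pure text or pure table
#' combinations are selectable via `load_parameters(variant = )`.
#'
#' @return A data.frame with columns `name`, `group`, `default`, `min`,
#'   `max`, `unit`, `description`.
#' @seealso [load_parameters()], [default_parameters()]
#' @export
parameter_registry <- function() {
  r <- function(name, group, default, min, max, unit, description) {
    data.frame(name = name, group = group, default = default, min = min,
               max = max, unit = unit, description = description,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # -- initial values ------------------------------------------------
    r("w_0",    "initial", 3.2,  1e-6, Inf, "g",    "initial fruit water mass"),
    r("s_0",    "initial", 0.5,  1e-6, Inf, "g",    "initial fruit dry matter"),
    r("P_f0",   "initial", 2,    -Inf, Inf, "bar",  "initial fruit turgor"),
    r("u_0",    "initial", 0.01, 0,    Inf, "g",    "initial starch mass"),
    # -- other solutes -------------------------------------------------
    r("pi_pO",  "solutes", 12.53, 0, Inf, "bar", "phloem osmotic pressure from non-sugar solutes"),
    r("pi_fO",  "solutes", 6.5,   0, Inf, "bar", "fruit osmotic pressure from non-sugar solutes"),
    # -- cell expansion ------------------------------------------------
    r("Y",      "expansion", 2,       0,    Inf, "bar",          "turgor yield threshold for plastic growth"),
    r("d_1",    "expansion", 15,      0,    Inf, "DAFB",         "end of cell-division extensibility plateau"),
    r("d_2",    "expansion", 60,      0,    Inf, "DAFB",         "end of log-linear extensibility transition"),
    r("phi_1",  "expansion", 0.2,     0,    Inf, "bar^-1 h^-1",  "extensibility during cell division"),
    r("phi_2",  "expansion", 0.000135, 0,  Inf, "bar^-1 h^-1",  "extensibility at end of transition"),
    r("phi_k",  "expansion", 0.028,   0,    Inf, "d^-1",         "late-season log-extensibility decline rate"),
    r("epsilon","expansion", 153,     0,    Inf, "bar",          "volumetric elastic modulus"),
    # -- active uptake -------------------------------------------------
    r("K_m",    "uptake", 0.08,  0, Inf, "g g^-1", "Michaelis constant of active sugar uptake"),
    r("nu_1",   "uptake", 0.005, 0, Inf, "h^-1",   "maximal active uptake per g dry matter at 20 C"),
    r("Q10_nu", "uptake", 2,     0, Inf, "1",      "Q10 of active uptake"),
    # -- membrane ------------------------------------------------------
    r("sigma_p","membrane", 0.9,    0, 1,   "1",                   "phloem membrane reflection coefficient"),
    r("sigma_x","membrane", 1,      0, 1,   "1",                   "xylem membrane reflection coefficient"),
    r("a_x",    "membrane", 0.066,  0, Inf, "1",                   "xylem membrane area fraction of fruit surface"),
    r("a_p",    "membrane", 0.066,  0, Inf, "1",                   "phloem membrane area fraction of fruit surface"),
    r("L_x",    "membrane", 0.0072, 0, Inf, "g cm^-2 bar^-1 h^-1", "xylem membrane hydraulic conductivity"),
    r("L_p",    "membrane", 0.0072, 0, Inf, "g cm^-2 bar^-1 h^-1", "phloem membrane hydraulic conductivity"),
    r("p_s",    "membrane", 0.003,  0, Inf, "cm h^-1",             "membrane solute permeability"),
    # -- skin permeance ------------------------------------------------
    r("rho_0",   "skin", 800,   0, Inf, "cm h^-1", "skin permeance at fit origin"),
    r("rho_inf", "skin", 25,    0, Inf, "cm h^-1", "late-season skin permeance asymptote"),
    r("k_rho",   "skin", 0.035, 0, Inf, "d^-1",    "skin permeance decline rate"),
    r("t_rho",   "skin", 18,    0, Inf, "DAFB",    "first day of the permeance decline"),
    # -- pedicel -------------------------------------------------------
    r("L1x",    "pedicel", 0.09,  0, Inf, "g h^-1 bar^-1", "pedicel xylem conductance rise amplitude"),
    r("L2x",    "pedicel", 0.02,  0, Inf, "g h^-1 bar^-1", "pedicel xylem conductance late plateau"),
    r("k1x",    "pedicel", 0.1,   0, Inf, "d^-1",          "pedicel xylem conductance rise rate"),
    r("k2x",    "pedicel", 0.036, 0, Inf, "d^-1",          "pedicel xylem conductance decline rate"),
    r("t_1",    "pedicel", 30,    0, Inf, "DAFB",          "pedicel conductance rise midpoint"),
    r("t_2",    "pedicel", 70,    0, Inf, "DAFB",          "pedicel xylem conductance decline midpoint"),
    r("Lp_inf", "pedicel", 0.016, 0, Inf, "g h^-1 bar^-1", "pedicel phloem conductance asymptote"),
    r("k1p",    "pedicel", 0.1,   0, Inf, "d^-1",          "pedicel phloem conductance rise rate"),
    # -- starch sub-model ----------------------------------------------
    r("A_o",   "starch", 0.56,   0, Inf, "1",    "structural dry-matter proportion amplitude"),
    r("k_o",   "starch", 0.0384, 0, Inf, "g^-1", "decay of structural proportion with dry mass"),
    r("s_b",   "starch", 3.8,    0, 100, "%",    "basal soluble solids percentage"),
    r("k_s1",  "starch", 0.5,    0, Inf, "d^-1", "maximal starch synthesis rate"),
    r("t_r",   "starch", 165,    0, Inf, "DAFB", "starch synthesis cutoff time"),
    r("t_h",   "starch", 25,     0, Inf, "d",    "e-folding lead time of synthesis decline"),
    r("k_u",   "starch", 0.0551, 0, Inf, "d^-1", "starch breakdown rate"),
    # -- respiration (peach-model values; see package documentation) ---
    r("q_m",   "respiration", 4.44e-4, 0, Inf, "h^-1", "maintenance respiration coefficient at 20 C"),
    r("q_g",   "respiration", 0.084,   0, Inf, "1",    "growth respiration coefficient"),
    r("Q10_r", "respiration", 1.9,     0, Inf, "1",    "Q10 of maintenance respiration"),
    # -- physical constants --------------------------------------------
    r("R_g",   "physical", 83.14, 0, Inf, "cm^3 bar mol^-1 K^-1", "gas constant"),
    r("M_s",   "physical", 342,   0, Inf, "g mol^-1",             "molar mass of sucrose"),
    r("M_w",   "physical", 18,    0, Inf, "g mol^-1",             "molar mass of water"),
    r("H_f",   "physical", 0.996, 0, 1,   "1",                    "relative humidity of internal air spaces"),
    r("rho_sol","physical", 1,    0, Inf, "g cm^-3",              "solution (and fruit) density convention"),
    # -- surface area --------------------------------------------------
    r("gamma", "area", 5.2076, 0, Inf, "cm^2 g^-eta", "surface-area allometry coefficient"),
    r("eta",   "area", 0.6424, 0, Inf, "1",           "surface-area allometry exponent")
  ))
}

# option flags: model-form choices that are selectable but not numeric
.kiwi_option_defaults <- function() {
  list(
    # functional form of structural dry matter: proportional A_o*s*exp(-k_o*s)
    # or saturating A_o*(1-exp(-k_o*s))
    starch_o_form      = "proportional",
    # basis of the basal-soluble-solids cap: fresh weight (w+s) or juice (w+s_s)
    s_b_base           = "fresh",
    # concentration multiplying the pedicel phloem flow in the sucrose
    # flux: "stem" (upstream plug-flow advection; conservative and
    # single-rooted, the default), "mean", or "fruit_end"
    pedicel_sugar_conc = "stem",
    # fruit-end closure: "pathway" = separate xylem and phloem mass
    # balances at the fruit end (Muench-type sap flow; default);
    # "equilibrium" = single total mass balance with the fruit-end
    # phloem in water-potential equilibrium with the fruit-end xylem
    pedicel_closure    = "pathway"
  )
}

.kiwi_variants <- list(
  base  = c(),
  text  = c(Y = 2,    phi_2 = 0.00135,  phi_k = 0.0028),
  table = c(Y = 0.08, phi_2 = 0.000135, phi_k = 0.028)
)

#' Default model parameters
#'
#' Convenience wrapper: `load_parameters()` with an empty source.
#'
#' @inheritParams load_parameters
#' @return A validated `kiwi_params` list.
#' @export
default_parameters <- function(variant = "base") {
  load_parameters(variant = variant)
}

#' Load and validate a model parameter set
#'
#' Builds the full parameter set from the registry defaults, then applies
#' overrides from `source` (a named list and/or a YAML/JSON file). Every
#' value is checked against the registry's admissible range and a handful
#' of cross-parameter constraints (`d_1 < d_2`, `t_h < t_r`, reflection
#' coefficients in \[0, 1\]). Unknown keys are an error, so typos cannot
#' silently fall back to defaults.
#'
#' @param source named list of overrides, or a path to a YAML or JSON
#'   parameter file (a flat `name: value` mapping, possibly with an
#'   `options` sub-mapping). `NULL` gives the full default set.
#' @param variant `"base"` (package defaults), `"text"` (the running-text
#'   values of `Y`, `phi_2`, `phi_k`) or `"table"` (the tabulated
#'   values); see [parameter_registry()].
#' @param options named list of model-form flags (`starch_o_form`,
#'   `s_b_base`, `pedicel_sugar_conc`); merged over the defaults.
#' @return A named list of class `kiwi_params`: all numeric parameters as
#'   scalars, plus an `options` element with the form flags.
#' @examples
#' p <- load_parameters()
#' p$epsilon            # 153 bar
#' p2 <- load_parameters(list(nu_1 = 0.006))
#' p2$nu_1
#' @export
load_parameters <- function(source = NULL, variant = c("base", "text", "table"),
                            options = list()) {
  variant <- match.arg(variant)
  reg <- parameter_registry()
  values <- as.list(stats::setNames(reg$default, reg$name))
  opts <- .kiwi_option_defaults()

  vv <- .kiwi_variants[[variant]]
  if (length(vv)) values[names(vv)] <- unname(vv)

  src <- list()
  if (is.character(source) && length(source) == 1L) {
    src <- .read_param_file(source)
  } else if (is.list(source)) {
    src <- source
  } else if (!is.null(source)) {
    stop("`source` must be NULL, a named list, or a file path", call. = FALSE)
  }

  if ("options" %in% names(src)) {
    options <- utils::modifyList(src$options, options)
    src$options <- NULL
  }

  if (length(src)) {
    if (is.null(names(src)) || any(names(src) == "")) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(src), reg$name)
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(src)) {
      v <- src[[nm]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
        stop("parameter '", nm, "' must be a single finite number",
             call. = FALSE)
      }
      values[[nm]] <- as.numeric(v)
    }
  }

  unknown_opt <- setdiff(names(options), names(opts))
  if (length(unknown_opt)) {
    stop("unknown option(s): ", paste(unknown_opt, collapse = ", "),
         call. = FALSE)
  }
  opts <- utils::modifyList(opts, options)
  .validate_options(opts)

  params <- values
  params$options <- opts
  class(params) <- "kiwi_params"
  validate_parameters(params)
  params
}

.read_param_file <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  src <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML 1.1 reads a bare key `Y` (the yield threshold) as boolean TRUE
  names(src)[names(src) == "TRUE"] <- "Y"
  src
}

.validate_options <- function(opts) {
  allowed <- list(starch_o_form = c("proportional", "saturating"),
                  s_b_base = c("fresh", "juice"),
                  pedicel_sugar_conc = c("stem", "mean", "fruit_end"),
                  pedicel_closure = c("pathway", "equilibrium"))
  for (nm in names(allowed)) {
    if (!is.character(opts[[nm]]) || !opts[[nm]] %in% allowed[[nm]]) {
      stop("option '", nm, "' must be one of: ",
           paste(allowed[[nm]], collapse = ", "), call. = FALSE)
    }
  }
  invisible(opts)
}

#' Validate a parameter set against the registry
#'
#' Checks range constraints from [parameter_registry()] plus the
#' cross-parameter invariants. Called by [load_parameters()]; exported so
#' that programmatically constructed sets can be re-checked.
#'
#' @param params a `kiwi_params` list.
#' @return `params`, invisibly; errors on any violation.
#' @export
validate_parameters <- function(params) {
  reg <- parameter_registry()
  missing <- setdiff(reg$name, names(params))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    }
    if (v < reg$min[i] || v > reg$max[i]) {
      stop(sprintf("parameter '%s' = %g outside its range [%g, %g] %s",
                   nm, v, reg$min[i], reg$max[i], reg$unit[i]), call. = FALSE)
    }
  }
  if (params$d_1 >= params$d_2) stop("d_1 must be < d_2", call. = FALSE)
  if (params$t_h >= params$t_r) stop("t_h must be < t_r", call. = FALSE)
  if (params$phi_1 <= params$phi_2) {
    stop("phi_1 must exceed phi_2 (extensibility declines between phases)",
         call. = FALSE)
  }
  if (params$rho_0 <= params$rho_inf) {
    stop("rho_0 must exceed rho_inf (skin permeance declines with age)",
         call. = FALSE)
  }
  invisible(params)
}

#' Write a parameter set to a YAML or JSON file
#'
#' The canonical on-disk format is a flat `name: value` mapping plus an
#' `options` sub-mapping. Numbers are written with full double precision so
#' that `load_parameters(path)` reproduces the set bit-exactly.
#'
#' @param params a `kiwi_params` list.
#' @param path output path; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "kiwi_params"))
  reg <- parameter_registry()
  vals <- params[reg$name]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(c(vals, list(options = params$options)), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    lines <- c("# kiwisim parameter file (units in parameter_registry())",
               vapply(seq_len(nrow(reg)), function(i) {
                 sprintf("\"%s\": %s  # %s; %s", reg$name[i],
                         format(vals[[reg$name[i]]], digits = 17),
                         reg$unit[i], reg$description[i])
               }, character(1)),
               "options:",
               vapply(names(params$options), function(nm) {
                 sprintf("  %s: %s", nm, params$options[[nm]])
               }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @export
print.kiwi_params <- function(x, ...) {
  reg <- parameter_registry()
  cat("<kiwi_params> ", nrow(reg), " model constants\n", sep = "")
  changed <- reg$name[vapply(reg$name, function(nm)
    !isTRUE(all.equal(x[[nm]], reg$default[reg$name == nm])), logical(1))]
  if (length(changed)) {
    cat("  non-default:",
        paste(sprintf("%s=%g", changed,
                      unlist(x[changed])), collapse = ", "), "\n")
  } else {
    cat("  all at registry defaults\n")
  }
  cat("  options:", paste(sprintf("%s=%s", names(x$options),
                                  unlist(x$options)), collapse = ", "), "\n")
  invisible(x)
}
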