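#' @useDynLib adcpbpk
#' @importFrom stats median qt quantile rlnorm rnorm runif sd setNames
#' @importFrom utils modifyList read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Compound domain types: ADC, small molecule (payload), perpetrator, victim.
# Parameter files are versioned YAML with units spelled out in field names so
# every shipped value can be audited against its source.
# ---------------------------------------------------------------------------

.adc_fields <- c(
  "schema", "name", "mw_adc_da", "max_dar", "dar_fractions", "kd_fcrn_um",
  "k_up_per_h", "k_rc1_per_h", "cl_cat_l_h", "cl_add_slope_l_h_per_dar",
  "k_dec_plasma_per_h", "k_dec_tissue_per_h", "f_rel_deconj", "f_rel_cat",
  "k_rel_cat_per_h", "notes"
)

.smallmol_fields <- c(
  "schema", "name", "mw_da", "ionization_class", "log_p", "pka", "bp_ratio",
  "fu_plasma", "kp_scalar", "vss_reference_l_kg", "clint_cyp3a4_ul_min_pmol",
  "cl_r_l_h", "clint_pgp_ul_min_10e6cells", "cl_pd_ml_min_10e6cells",
  "cl_iv_reference_l_h", "f_bile", "ki_cyp3a4_rev_um", "kapp_um",
  "kinact_per_h", "ki_pgp_um", "notes"
)

.perp_fields <- c(
  "schema", "name", "mw_da", "model", "ka_per_h", "v1_l", "v2_l", "q12_l_h",
  "cl_l_h", "fu_plasma", "f_oral", "ki_cyp3a4_um", "kapp_um", "kinact_per_h",
  "ind_max", "ind_c50_um", "ki_pgp_um", "pgp_raf_fold", "notes"
)

.victim_fields <- c(
  "schema", "name", "mw_da", "ka_per_h", "v1_l", "v2_l", "q12_l_h",
  "fu_plasma", "bp_ratio", "clint_cyp3a4_u_l_h", "cl_r_l_h", "cl_pgp_l_h",
  "f_oral", "fg_pgp_gain", "pgp_raf_fold", "notes"
)

.assert_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("field '%s' must be a single number", name), call. = FALSE)
  if (x < lo || x > hi)
    stop(sprintf("field '%s' = %g outside [%g, %g]", name, x, lo, hi),
         call. = FALSE)
  as.numeric(x)
}

.check_fields <- function(x, allowed, required, kind) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("%s file has unknown field(s): %s", kind,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(sprintf("%s file is missing field(s): %s", kind,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

#' Construct a validated ADC compound
#'
#' Holds the drug-to-antibody-ratio (DAR) distribution, FcRn affinity and the
#' rate constants of the DAR-stratified minimal PBPK antibody model.
#'
#' @param mw_adc_da antibody molecular mass (Da)
#' @param max_dar maximum DAR (integer)
#' @param dar_fractions probabilities of DAR species `0..max_dar`
#'   (length `max_dar + 1`, non-negative, summing to 1 within 1e-6)
#' @param kd_fcrn_um FcRn dissociation constant at pH 6.0 (uM)
#' @param k_up_per_h endosomal uptake rate constant (1/h)
#' @param k_rc1_per_h recycle rate constant (1/h)
#' @param cl_cat_l_h catabolic clearance (L/h)
#' @param cl_add_slope_l_h_per_dar additional systemic clearance per DAR unit
#'   (L/h per DAR)
#' @param k_dec_plasma_per_h plasma deconjugation rate constant (1/h)
#' @param k_dec_tissue_per_h tissue (endosomal) deconjugation rate constant (1/h)
#' @param f_rel_deconj fraction of payload released on deconjugation
#' @param f_rel_cat fraction of payload released on catabolism
#' @param k_rel_cat_per_h release rate constant from the catabolite depot (1/h)
#' @param name compound label
#' @param notes free-text provenance notes carried through file round-trips
#' @return an object of class `adc_compound`
#' @export
adc_compound <- function(mw_adc_da, max_dar, dar_fractions, kd_fcrn_um,
                         k_up_per_h, k_rc1_per_h, cl_cat_l_h,
                         cl_add_slope_l_h_per_dar, k_dec_plasma_per_h,
                         k_dec_tissue_per_h, f_rel_deconj, f_rel_cat,
                         k_rel_cat_per_h, name = "adc", notes = NULL) {
  max_dar <- .assert_scalar(max_dar, "max_dar", 1, 16)
  if (max_dar != round(max_dar)) stop("max_dar must be an integer")
  if (!is.numeric(dar_fractions) || length(dar_fractions) != max_dar + 1L)
    stop(sprintf("dar_fractions must have length max_dar + 1 = %d",
                 max_dar + 1L), call. = FALSE)
  if (any(dar_fractions < 0))
    stop("dar_fractions must be non-negative", call. = FALSE)
  if (abs(sum(dar_fractions) - 1) > 1e-6)
    stop(sprintf("dar_fractions must sum to 1 within 1e-6 (got %.8f)",
                 sum(dar_fractions)), call. = FALSE)
  obj <- list(
    name = as.character(name),
    mw_adc_da = .assert_scalar(mw_adc_da, "mw_adc_da", 1e4, 1e6),
    max_dar = as.integer(max_dar),
    dar_fractions = as.numeric(dar_fractions),
    kd_fcrn_um = .assert_scalar(kd_fcrn_um, "kd_fcrn_um", 0),
    k_up_per_h = .assert_scalar(k_up_per_h, "k_up_per_h", 0),
    k_rc1_per_h = .assert_scalar(k_rc1_per_h, "k_rc1_per_h", 0),
    cl_cat_l_h = .assert_scalar(cl_cat_l_h, "cl_cat_l_h", 0),
    cl_add_slope_l_h_per_dar =
      .assert_scalar(cl_add_slope_l_h_per_dar, "cl_add_slope_l_h_per_dar", 0),
    k_dec_plasma_per_h = .assert_scalar(k_dec_plasma_per_h,
                                        "k_dec_plasma_per_h", 0),
    k_dec_tissue_per_h = .assert_scalar(k_dec_tissue_per_h,
                                        "k_dec_tissue_per_h", 0),
    f_rel_deconj = .assert_scalar(f_rel_deconj, "f_rel_deconj", 0, 1),
    f_rel_cat = .assert_scalar(f_rel_cat, "f_rel_cat", 0, 1),
    k_rel_cat_per_h = .assert_scalar(k_rel_cat_per_h, "k_rel_cat_per_h", 0),
    notes = notes
  )
  class(obj) <- c("adc_compound", "compound")
  obj
}

#' Construct a validated small-molecule (payload) compound
#'
#' Physicochemistry, clearances and interaction constants of the released
#' payload modelled with the whole-body PBPK approach.
#'
#' @param mw_da molecular mass (Da)
#' @param ionization_class currently only `"monoprotic base"`
#' @param log_p octanol-water log partition coefficient
#' @param pka basic pKa
#' @param bp_ratio blood-to-plasma concentration ratio
#' @param fu_plasma unbound fraction in plasma
#' @param kp_scalar global multiplier on predicted tissue partition
#'   coefficients (matches the observed steady-state volume)
#' @param vss_reference_l_kg reference steady-state volume of distribution (L/kg)
#' @param clint_cyp3a4_ul_min_pmol intrinsic CYP3A4 clearance (uL/min/pmol)
#' @param cl_r_l_h renal clearance (L/h)
#' @param clint_pgp_ul_min_10e6cells P-gp transporter intrinsic clearance
#'   (uL/min/million hepatocytes)
#' @param cl_pd_ml_min_10e6cells passive diffusion clearance into hepatocytes
#'   (mL/min/million hepatocytes)
#' @param cl_iv_reference_l_h apparent systemic clearance anchoring the
#'   retrograde calculation (L/h)
#' @param f_bile biliary fraction of hepatic (non-renal) clearance
#' @param ki_cyp3a4_rev_um reversible CYP3A4 inhibition constant (uM)
#' @param kapp_um unbound concentration at half-maximal inactivation rate (uM)
#' @param kinact_per_h maximal CYP3A4 inactivation rate (1/h)
#' @param ki_pgp_um reversible P-gp inhibition constant (uM)
#' @param name compound label
#' @param notes provenance notes
#' @return an object of class `smallmol_compound`
#' @export
small_molecule_compound <- function(mw_da, ionization_class, log_p, pka,
                                    bp_ratio, fu_plasma, kp_scalar,
                                    vss_reference_l_kg,
                                    clint_cyp3a4_ul_min_pmol, cl_r_l_h,
                                    clint_pgp_ul_min_10e6cells,
                                    cl_pd_ml_min_10e6cells,
                                    cl_iv_reference_l_h, f_bile,
                                    ki_cyp3a4_rev_um, kapp_um, kinact_per_h,
                                    ki_pgp_um, name = "small molecule",
                                    notes = NULL) {
  cl_iv <- .assert_scalar(cl_iv_reference_l_h, "cl_iv_reference_l_h", 0)
  cl_r <- .assert_scalar(cl_r_l_h, "cl_r_l_h", 0)
  if (cl_r > cl_iv)
    stop("cl_r_l_h may not exceed cl_iv_reference_l_h", call. = FALSE)
  obj <- list(
    name = as.character(name),
    mw_da = .assert_scalar(mw_da, "mw_da", 50, 5000),
    ionization_class = match.arg(ionization_class, "monoprotic base"),
    log_p = .assert_scalar(log_p, "log_p", -5, 10),
    pka = .assert_scalar(pka, "pka", 0, 14),
    bp_ratio = .assert_scalar(bp_ratio, "bp_ratio", 0),
    fu_plasma = .assert_scalar(fu_plasma, "fu_plasma", 0, 1),
    kp_scalar = .assert_scalar(kp_scalar, "kp_scalar", 0),
    vss_reference_l_kg = .assert_scalar(vss_reference_l_kg,
                                        "vss_reference_l_kg", 0),
    clint_cyp3a4_ul_min_pmol = .assert_scalar(clint_cyp3a4_ul_min_pmol,
                                              "clint_cyp3a4_ul_min_pmol", 0),
    cl_r_l_h = cl_r,
    clint_pgp_ul_min_10e6cells = .assert_scalar(
      clint_pgp_ul_min_10e6cells, "clint_pgp_ul_min_10e6cells", 0),
    cl_pd_ml_min_10e6cells = .assert_scalar(cl_pd_ml_min_10e6cells,
                                            "cl_pd_ml_min_10e6cells", 0),
    cl_iv_reference_l_h = cl_iv,
    f_bile = .assert_scalar(f_bile, "f_bile", 0, 1),
    ki_cyp3a4_rev_um = .assert_scalar(ki_cyp3a4_rev_um, "ki_cyp3a4_rev_um", 0),
    kapp_um = .assert_scalar(kapp_um, "kapp_um", 0),
    kinact_per_h = .assert_scalar(kinact_per_h, "kinact_per_h", 0),
    ki_pgp_um = .assert_scalar(ki_pgp_um, "ki_pgp_um", 0),
    notes = notes
  )
  class(obj) <- c("smallmol_compound", "compound")
  obj
}

#' Construct a validated perpetrator compound
#'
#' One/two-compartment oral PK model plus the interaction block (reversible
#' CYP3A4 inhibition, mechanism-based inactivation, turnover induction,
#' reversible P-gp inhibition, and a manual P-gp relative-activity-factor fold
#' for transporter induction).
#'
#' @param mw_da molecular mass (Da)
#' @param model `"one_compartment"` or `"two_compartment"`
#' @param ka_per_h first-order absorption rate constant (1/h)
#' @param v1_l central volume (L)
#' @param v2_l peripheral volume (L, 0 for one-compartment)
#' @param q12_l_h inter-compartment clearance (L/h)
#' @param cl_l_h systemic clearance (L/h)
#' @param fu_plasma unbound plasma fraction
#' @param f_oral absolute oral bioavailability
#' @param ki_cyp3a4_um reversible CYP3A4 inhibition constant (uM, 0 = none)
#' @param kapp_um MBI half-maximal unbound concentration (uM, 0 = no MBI)
#' @param kinact_per_h MBI maximal inactivation rate (1/h)
#' @param ind_max maximal fold-increase of enzyme synthesis minus one
#'   (0 = no induction)
#' @param ind_c50_um unbound concentration at half-maximal induction (uM)
#' @param ki_pgp_um reversible P-gp inhibition constant (uM, 0 = none)
#' @param pgp_raf_fold static multiplier applied to victim P-gp intrinsic
#'   clearance in the with-perpetrator arm (>= 1 for inducers, 1 otherwise)
#' @param name compound label
#' @param notes provenance notes
#' @return an object of class `perpetrator_compound`
#' @export
perpetrator_compound <- function(mw_da, model, ka_per_h, v1_l, v2_l, q12_l_h,
                                 cl_l_h, fu_plasma, f_oral, ki_cyp3a4_um,
                                 kapp_um, kinact_per_h, ind_max, ind_c50_um,
                                 ki_pgp_um, pgp_raf_fold, name = "perpetrator",
                                 notes = NULL) {
  model <- match.arg(model, c("one_compartment", "two_compartment"))
  v2 <- .assert_scalar(v2_l, "v2_l", 0)
  if (model == "one_compartment" && v2 != 0)
    stop("one_compartment model must have v2_l = 0", call. = FALSE)
  if (model == "two_compartment" && v2 <= 0)
    stop("two_compartment model needs v2_l > 0", call. = FALSE)
  raf <- .assert_scalar(pgp_raf_fold, "pgp_raf_fold", 0)
  ind_max <- .assert_scalar(ind_max, "ind_max", 0)
  if (ind_max > 0 && raf < 1)
    stop("pgp_raf_fold must be >= 1 for inducers", call. = FALSE)
  if (ind_max == 0 && raf != 1)
    stop("pgp_raf_fold must be 1 for non-inducers", call. = FALSE)
  obj <- list(
    name = as.character(name),
    mw_da = .assert_scalar(mw_da, "mw_da", 50, 5000),
    model = model,
    ka_per_h = .assert_scalar(ka_per_h, "ka_per_h", 0),
    v1_l = .assert_scalar(v1_l, "v1_l", 1e-6),
    v2_l = v2,
    q12_l_h = .assert_scalar(q12_l_h, "q12_l_h", 0),
    cl_l_h = .assert_scalar(cl_l_h, "cl_l_h", 0),
    fu_plasma = .assert_scalar(fu_plasma, "fu_plasma", 0, 1),
    f_oral = .assert_scalar(f_oral, "f_oral", 0, 1),
    ki_cyp3a4_um = .assert_scalar(ki_cyp3a4_um, "ki_cyp3a4_um", 0),
    kapp_um = .assert_scalar(kapp_um, "kapp_um", 0),
    kinact_per_h = .assert_scalar(kinact_per_h, "kinact_per_h", 0),
    ind_max = ind_max,
    ind_c50_um = .assert_scalar(ind_c50_um, "ind_c50_um", 0),
    ki_pgp_um = .assert_scalar(ki_pgp_um, "ki_pgp_um", 0),
    pgp_raf_fold = raf,
    notes = notes
  )
  class(obj) <- c("perpetrator_compound", "compound")
  obj
}

#' Construct a validated victim compound
#'
#' Reduced (two-compartment) disposition model for probe substrates such as
#' midazolam (CYP3A4) and digoxin (P-gp): well-stirred hepatic CYP3A4
#' clearance from unbound intrinsic clearance, a modifiable P-gp pathway
#' clearance, renal clearance, and optional first-order oral absorption with
#' an intestinal P-gp bioavailability term.
#'
#' @param mw_da molecular mass (Da)
#' @param ka_per_h absorption rate constant (1/h)
#' @param v1_l central volume (L)
#' @param v2_l peripheral volume (L)
#' @param q12_l_h inter-compartment clearance (L/h)
#' @param fu_plasma unbound plasma fraction
#' @param bp_ratio blood-to-plasma ratio
#' @param clint_cyp3a4_u_l_h unbound hepatic CYP3A4 intrinsic clearance (L/h)
#' @param cl_r_l_h renal clearance (L/h)
#' @param cl_pgp_l_h P-gp-mediated pathway clearance (L/h, plasma)
#' @param f_oral baseline oral bioavailability
#' @param fg_pgp_gain maximal fractional bioavailability increase under
#'   complete intestinal P-gp inhibition
#' @param pgp_raf_fold fold applied to the P-gp pathway when a transporter
#'   inducer is co-administered (1 = none)
#' @param name compound label
#' @param notes provenance notes
#' @return an object of class `victim_compound`
#' @export
victim_compound <- function(mw_da, ka_per_h, v1_l, v2_l, q12_l_h, fu_plasma,
                            bp_ratio, clint_cyp3a4_u_l_h, cl_r_l_h,
                            cl_pgp_l_h, f_oral, fg_pgp_gain = 0,
                            pgp_raf_fold = 1, name = "victim", notes = NULL) {
  obj <- list(
    name = as.character(name),
    mw_da = .assert_scalar(mw_da, "mw_da", 50, 5000),
    ka_per_h = .assert_scalar(ka_per_h, "ka_per_h", 0),
    v1_l = .assert_scalar(v1_l, "v1_l", 1e-6),
    v2_l = .assert_scalar(v2_l, "v2_l", 0),
    q12_l_h = .assert_scalar(q12_l_h, "q12_l_h", 0),
    fu_plasma = .assert_scalar(fu_plasma, "fu_plasma", 0, 1),
    bp_ratio = .assert_scalar(bp_ratio, "bp_ratio", 1e-6),
    clint_cyp3a4_u_l_h = .assert_scalar(clint_cyp3a4_u_l_h,
                                        "clint_cyp3a4_u_l_h", 0),
    cl_r_l_h = .assert_scalar(cl_r_l_h, "cl_r_l_h", 0),
    cl_pgp_l_h = .assert_scalar(cl_pgp_l_h, "cl_pgp_l_h", 0),
    f_oral = .assert_scalar(f_oral, "f_oral", 0, 1),
    fg_pgp_gain = .assert_scalar(fg_pgp_gain, "fg_pgp_gain", 0),
    pgp_raf_fold = .assert_scalar(pgp_raf_fold, "pgp_raf_fold", 0),
    notes = notes
  )
  class(obj) <- c("victim_compound", "compound")
  obj
}

.compound_schemas <- c(
  adc = "adc_compound/1",
  smallmol = "small_molecule_compound/1",
  perpetrator = "perpetrator_compound/1",
  victim = "victim_compound/1"
)

#' Load a compound parameter file
#'
#' Reads a versioned YAML compound file, enforces the schema (unknown keys
#' rejected, all required fields present) and returns the validated compound
#' object. The compound class is inferred from the `schema` field unless
#' `kind` is given.
#'
#' @param path path to a compound YAML file
#' @param kind optional: one of `"adc"`, `"smallmol"`, `"perpetrator"`,
#'   `"victim"`; checked against the file's `schema` field
#' @return a validated compound object
#' @export
load_compound <- function(path, kind = NULL) {
  if (!file.exists(path))
    stop(sprintf("compound file not found: %s", path), call. = FALSE)
  x <- yaml::read_yaml(path)
  if (is.null(x$schema))
    stop(sprintf("%s: missing 'schema' field", path), call. = FALSE)
  inferred <- names(.compound_schemas)[match(x$schema, .compound_schemas)]
  if (is.na(inferred))
    stop(sprintf("%s: unknown schema '%s'", path, x$schema), call. = FALSE)
  if (!is.null(kind) && kind != inferred)
    stop(sprintf("%s: schema '%s' does not match requested kind '%s'",
                 path, x$schema, kind), call. = FALSE)
  kind <- inferred
  ctor_args <- function(required) {
    .check_fields(x, allowed = switch(kind,
                                      adc = .adc_fields,
                                      smallmol = .smallmol_fields,
                                      perpetrator = .perp_fields,
                                      victim = .victim_fields),
                  required = required, kind = kind)
    x[setdiff(names(x), "schema")]
  }
  obj <- switch(kind,
    adc = do.call(adc_compound, ctor_args(setdiff(.adc_fields,
                                                  c("schema", "notes")))),
    smallmol = do.call(small_molecule_compound,
                       ctor_args(setdiff(.smallmol_fields,
                                         c("schema", "notes")))),
    perpetrator = do.call(perpetrator_compound,
                          ctor_args(setdiff(.perp_fields,
                                            c("schema", "notes")))),
    victim = do.call(victim_compound,
                     ctor_args(setdiff(.victim_fields, c("schema", "notes"))))
  )
  attr(obj, "source_file") <- normalizePath(path)
  obj
}

#' Write a compound back to a parameter file
#'
#' Inverse of [load_compound()]: numeric fields round-trip bit-exactly
#' (values are serialised at full double precision).
#'
#' @param compound a compound object
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_compound <- function(compound, path) {
  kind <- switch(class(compound)[1],
                 adc_compound = "adc",
                 smallmol_compound = "smallmol",
                 perpetrator_compound = "perpetrator",
                 victim_compound = "victim",
                 stop("not a compound object"))
  x <- unclass(compound)
  x$max_dar <- if (!is.null(x$max_dar)) as.numeric(x$max_dar)
  x <- c(list(schema = unname(.compound_schemas[kind])), x)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' Path to a shipped default compound file
#'
#' @param name compound file stem, e.g. `"enfortumab_vedotin"`, `"mmae"`,
#'   `"ketoconazole"`, `"rifampin"`, `"midazolam"`, `"digoxin"`,
#'   `"brentuximab_vedotin"`; with no argument, lists available stems.
#' @return a file path, or a character vector of stems
#' @export
default_compound_file <- function(name = NULL) {
  dir <- system.file("extdata", "compounds", package = "adcpbpk")
  if (is.null(name))
    return(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
  path <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(path))
    stop(sprintf("no shipped compound file '%s'", name), call. = FALSE)
  path
}

#' Mean drug-to-antibody ratio of a DAR distribution
#'
#' @param dar_fractions probability vector over DAR species `0..max_dar`
#' @return the weighted mean DAR, `sum(j * p_j)`
#' @export
mean_dar <- function(dar_fractions) {
  if (!is.numeric(dar_fractions) || any(is.na(dar_fractions)) ||
      any(dar_fractions < 0))
    stop("dar_fractions must be non-negative numbers", call. = FALSE)
  if (abs(sum(dar_fractions) - 1) > 1e-6)
    stop("dar_fractions must sum to 1 within 1e-6", call. = FALSE)
  sum((seq_along(dar_fractions) - 1) * dar_fractions)
}

#' Retrograde split of systemic clearance into biliary and metabolic routes
#'
#' Back-derives the hepatic pathway clearances from an observed apparent
#' systemic clearance: hepatic clearance is the non-renal remainder, of which
#' a fraction `f_bile` is biliary (P-gp) and the rest metabolic (100% CYP3A4).
#'
#' @param cl_iv apparent systemic clearance (L/h)
#' @param cl_r renal clearance (L/h), must not exceed `cl_iv`
#' @param f_bile biliary fraction of hepatic clearance, in `[0, 1]`
#' @return list with `cl_bile` and `cl_met_cyp3a4` (L/h); together with
#'   `cl_r` these always sum to `cl_iv`
#' @export
retrograde_split <- function(cl_iv, cl_r, f_bile) {
  cl_iv <- .assert_scalar(cl_iv, "cl_iv", 0)
  cl_r <- .assert_scalar(cl_r, "cl_r", 0)
  f_bile <- .assert_scalar(f_bile, "f_bile", 0, 1)
  if (cl_r > cl_iv)
    stop("cl_r may not exceed cl_iv", call. = FALSE)
  hepatic <- cl_iv - cl_r
  list(cl_bile = f_bile * hepatic, cl_met_cyp3a4 = (1 - f_bile) * hepatic)
}
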