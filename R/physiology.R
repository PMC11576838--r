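# Physiology sets, mechanistic tissue partitioning (Rodgers & Rowland) and
# liver clearance scaling. Organ volumes/flows and in-vitro-to-in-vivo
# scaling factors are literature defaults (documented per value in the
# shipped physiology file); the payload's whole-liver intrinsic clearances
# are anchored by the retrograde calculation against the reference systemic
# clearance rather than by the bottom-up scaling factors.

.pbpk_tissues <- c("adipose", "bone", "brain", "gut", "heart", "kidney",
                   "muscle", "skin", "spleen", "pancreas")

.phys_cache <- new.env(parent = emptyenv())

# cached copy of the shipped reference physiology (unscaled)
.reference_physiology <- function() {
  if (is.null(.phys_cache$ref))
    .phys_cache$ref <- load_physiology(
      system.file("extdata", "physiology", "adult_reference.yaml",
                  package = "adcpbpk"))
  .phys_cache$ref
}

#' Load a physiology set from a structured-text file
#'
#' @param path YAML physiology file (see the shipped
#'   `extdata/physiology/adult_reference.yaml` for the schema)
#' @return an object of class `physiology_set` (reference individual,
#'   unscaled)
#' @export
load_physiology <- function(path) {
  x <- yaml::read_yaml(path)
  req <- c("schema", "body_weight_kg", "hematocrit", "plasma_albumin_g_l",
           "plasma_volume_l_kg", "endosomal_volume_l", "fcrn_um",
           "liver_weight_g", "mppgl_mg_g", "hepatocellularity_10e6_g",
           "cyp3a4_abundance_pmol_mg", "cyp3a4_kdeg_per_h",
           "volumes_l", "flows_l_h")
  missing <- setdiff(req, names(x))
  if (length(missing))
    stop("physiology file missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!identical(x$schema, "physiology_set/1"))
    stop("unsupported physiology schema: ", x$schema, call. = FALSE)
  vols <- unlist(x$volumes_l)
  flows <- unlist(x$flows_l_h)
  need_v <- c(.pbpk_tissues, "lung", "liver", "venous_blood",
              "arterial_blood")
  need_q <- c(.pbpk_tissues, "hepatic_artery")
  if (!all(need_v %in% names(vols)))
    stop("physiology volumes incomplete", call. = FALSE)
  if (!all(need_q %in% names(flows)))
    stop("physiology flows incomplete", call. = FALSE)
  if (any(vols <= 0) || any(flows <= 0))
    stop("volumes and flows must be positive", call. = FALSE)
  obj <- x
  obj$volumes_l <- vols
  obj$flows_l_h <- flows
  class(obj) <- "physiology_set"
  obj
}

#' Reference adult physiology, scaled to a subject
#'
#' Loads the shipped reference physiology and applies allometric scaling:
#' organ volumes scale linearly with body weight, blood flows with
#' weight^0.75. The minimal-PBPK plasma volume additionally carries the
#' population tissue-volume scaling factor for plasma.
#'
#' @param weight_kg body weight (kg)
#' @param plasma_scaling tissue-volume scaling factor for plasma
#'   (1.0 in the modified cancer population; 1.2 unmodified)
#' @param hematocrit optional hematocrit override (fraction)
#' @param albumin_g_l optional plasma albumin override (g/L)
#' @return a `physiology_set` for the subject
#' @export
default_physiology <- function(weight_kg = 70, plasma_scaling = 1.0,
                               hematocrit = NULL, albumin_g_l = NULL) {
  ref <- .reference_physiology()
  wr <- weight_kg / ref$body_weight_kg
  ref$volumes_l <- ref$volumes_l * wr
  ref$flows_l_h <- ref$flows_l_h * wr^0.75
  ref$liver_weight_g <- ref$liver_weight_g * wr
  ref$endosomal_volume_l <- ref$endosomal_volume_l * wr
  ref$body_weight_kg <- weight_kg
  ref$plasma_scaling <- plasma_scaling
  ref$plasma_volume_l <- ref$plasma_volume_l_kg * weight_kg * plasma_scaling
  if (!is.null(hematocrit)) ref$hematocrit <- hematocrit
  if (!is.null(albumin_g_l)) ref$plasma_albumin_g_l <- albumin_g_l
  ref
}

# Tissue composition fractions for the mechanistic partition equations
# (extracellular water, intracellular water, neutral lipid, neutral
# phospholipid, acidic phospholipid mg/g). Standard published values used
# across open PBPK implementations.
.tissue_composition <- data.frame(
  tissue = c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
             "lung", "muscle", "skin", "spleen", "pancreas"),
  f_ew = c(0.135, 0.100, 0.162, 0.282, 0.320, 0.273, 0.161, 0.336, 0.118,
           0.382, 0.207, 0.120),
  f_iw = c(0.017, 0.346, 0.620, 0.475, 0.456, 0.483, 0.573, 0.446, 0.630,
           0.291, 0.579, 0.664),
  f_nl = c(0.853, 0.017, 0.039, 0.038, 0.014, 0.012, 0.014, 0.022, 0.010,
           0.060, 0.0077, 0.041),
  f_np = c(0.0016, 0.0017, 0.0015, 0.0125, 0.0111, 0.0242, 0.0240, 0.0128,
           0.0072, 0.0044, 0.0113, 0.0093),
  ap_mg_g = c(0.40, 0.67, 0.40, 2.41, 2.25, 5.03, 4.56, 3.91, 1.53, 1.32,
              3.18, 1.67),
  stringsAsFactors = FALSE
)

# blood cell composition (for deriving acidic-phospholipid association from
# the blood-to-plasma ratio)
.bc_composition <- list(f_iw = 0.603, f_nl = 0.0017, f_np = 0.0029,
                        ap_mg_g = 0.5, ph = 7.22)

#' Mechanistic tissue-to-plasma partition coefficients (monoprotic base)
#'
#' Tissue-composition partitioning for a monoprotic base: ionisation at
#' intracellular pH, partitioning into neutral lipid and neutral
#' phospholipid, and electrostatic association of the ionised species with
#' acidic phospholipids calibrated from blood-cell binding (derived from the
#' blood-to-plasma ratio and hematocrit). Each Kp is multiplied by the
#' compound's global `kp_scalar`.
#'
#' @param compound a [small_molecule_compound()] (must be a monoprotic base)
#' @param physiology a `physiology_set`
#' @return named list of tissue-to-plasma Kp values (class `kp_set`)
#' @export
kp_rodgers_rowland <- function(compound, physiology) {
  if (!inherits(compound, "smallmol_compound"))
    stop("compound must be a small-molecule compound", call. = FALSE)
  if (compound$ionization_class != "monoprotic base")
    stop("unsupported ionization class: ", compound$ionization_class,
         call. = FALSE)
  p_ow <- 10^compound$log_p
  pka <- compound$pka
  fu <- compound$fu_plasma
  hct <- physiology$hematocrit
  x_pl <- 1 + 10^(pka - 7.4)          # plasma ionisation (pH 7.4)
  x_iw <- 1 + 10^(pka - 7.0)          # intracellular water (pH 7.0)
  x_bc <- 1 + 10^(pka - .bc_composition$ph)

  # association constant of the ionised base with acidic phospholipids,
  # from red-blood-cell partitioning
  kpu_bc <- (compound$bp_ratio - (1 - hct)) / (hct * fu)
  lip_bc <- (p_ow * .bc_composition$f_nl +
             (0.3 * p_ow + 0.7) * .bc_composition$f_np) / x_pl
  ka_ap <- (kpu_bc - (x_bc / x_pl) * .bc_composition$f_iw - lip_bc) *
    x_pl / (.bc_composition$ap_mg_g * (x_bc - 1))
  ka_ap <- max(ka_ap, 0)

  comp <- .tissue_composition
  kpu <- comp$f_ew +
    (x_iw / x_pl) * comp$f_iw +
    (p_ow * comp$f_nl + (0.3 * p_ow + 0.7) * comp$f_np) / x_pl +
    ka_ap * comp$ap_mg_g * (x_iw - 1) / x_pl
  kp <- setNames(kpu * fu * compound$kp_scalar, comp$tissue)
  structure(as.list(kp), class = "kp_set")
}

#' Steady-state volume of distribution from a Kp set
#'
#' `Vss = V_plasma-equivalent blood + sum(V_t * Kp_t)` per kg body weight
#' (blood pool volumes referenced to plasma through the blood-to-plasma
#' ratio; the permeability-limited liver contributes its extracellular water
#' plus intracellular `Kp`-partitioned space).
#'
#' @param kps a `kp_set` from [kp_rodgers_rowland()]
#' @param physiology a `physiology_set`
#' @param compound the small-molecule compound (for the blood-to-plasma ratio)
#' @return Vss in L/kg
#' @export
vss_from_kp <- function(kps, physiology, compound) {
  v <- physiology$volumes_l
  liver_split <- .liver_spaces(physiology)
  kp_liv_ic <- .kp_liver_ic(kps, physiology)
  vss <- compound$bp_ratio * (v[["venous_blood"]] + v[["arterial_blood"]]) +
    v[["lung"]] * .kp_liver_or(kps, "lung") +
    sum(vapply(.pbpk_tissues,
               function(t) v[[t]] * kps[[t]], numeric(1))) +
    liver_split$v_ec + liver_split$v_ic * kp_liv_ic
  unname(vss / physiology$body_weight_kg)
}

.kp_liver_or <- function(kps, tissue) kps[[tissue]]

# extracellular/intracellular split of the liver (fractions of total liver
# volume; extracellular treated as plasma-like water)
.liver_spaces <- function(physiology) {
  v_liv <- physiology$volumes_l[["liver"]]
  list(v_ec = 0.25 * v_liv, v_ic = 0.75 * v_liv)
}

# intracellular liver partition coefficient consistent with the whole-organ
# Kp: V_ec * 1 + V_ic * Kp_ic = V_liver * Kp_liver
.kp_liver_ic <- function(kps, physiology) {
  s <- .liver_spaces(physiology)
  v_liv <- physiology$volumes_l[["liver"]]
  max((v_liv * kps$liver - s$v_ec) / s$v_ic, 1e-3)
}

#' Whole-liver clearance scaling from in-vitro units
#'
#' Bottom-up in-vitro-to-in-vivo extrapolation: CYP3A4 intrinsic clearance
#' scales with enzyme abundance, microsomal protein per gram liver and liver
#' weight; transporter and passive-diffusion clearances scale with
#' hepatocellularity and liver weight. A transporter relative activity
#' factor multiplies the P-gp term.
#'
#' @param compound a [small_molecule_compound()]
#' @param physiology a `physiology_set`
#' @param raf_pgp relative activity factor applied to the transporter (1.0
#'   default)
#' @return list with whole-liver unbound clearances (L/h):
#'   `clint_met`, `clint_pgp`, `cl_pd`
#' @export
scale_liver_clearances <- function(compound, physiology, raf_pgp = 1.0) {
  lw <- physiology$liver_weight_g
  mppgl <- physiology$mppgl_mg_g
  hep <- physiology$hepatocellularity_10e6_g
  abund <- physiology$cyp3a4_abundance_pmol_mg
  # uL/min/pmol * pmol/mg * mg/g * g -> uL/min -> L/h
  clint_met <- compound$clint_cyp3a4_ul_min_pmol * abund * mppgl * lw *
    60 / 1e6
  # uL/min/1e6 cells * 1e6 cells/g * g -> uL/min -> L/h
  clint_pgp <- compound$clint_pgp_ul_min_10e6cells * hep * lw * 60 / 1e6 *
    raf_pgp
  # mL/min/1e6 cells * 1e6 cells/g * g -> mL/min -> L/h
  cl_pd <- compound$cl_pd_ml_min_10e6cells * hep * lw * 60 / 1e3
  list(clint_met = clint_met, clint_pgp = clint_pgp, cl_pd = cl_pd)
}

#' Retrograde whole-liver intrinsic clearances
#'
#' Anchors the liver model to the compound's apparent systemic clearance:
#' the hepatic plasma clearance (`cl_iv - cl_r`) is inverted through the
#' well-stirred relation to a total unbound intrinsic clearance, which is
#' split into the biliary (P-gp) and metabolic (CYP3A4) routes by `f_bile`.
#'
#' @param compound a [small_molecule_compound()]
#' @param physiology a `physiology_set`
#' @param f_bile optional override of the compound's biliary fraction
#' @return list with `clint_met`, `clint_pgp` (whole-liver unbound L/h) and
#'   the implied hepatic plasma clearance `cl_h_plasma`
#' @export
retrograde_liver_clearances <- function(compound, physiology, f_bile = NULL) {
  if (is.null(f_bile)) f_bile <- compound$f_bile
  split <- retrograde_split(compound$cl_iv_reference_l_h, compound$cl_r_l_h,
                            f_bile)
  cl_h_plasma <- split$cl_bile + split$cl_met_cyp3a4
  q_h <- .hepatic_flow(physiology)
  fu_b <- compound$fu_plasma / compound$bp_ratio
  cl_h_blood <- cl_h_plasma / compound$bp_ratio
  if (cl_h_blood >= q_h)
    stop("hepatic clearance exceeds liver blood flow", call. = FALSE)
  clint_total <- q_h * cl_h_blood / (q_h - cl_h_blood) / fu_b
  list(clint_met = (1 - f_bile) * clint_total,
       clint_pgp = f_bile * clint_total,
       cl_h_plasma = cl_h_plasma)
}

.hepatic_flow <- function(physiology) {
  q <- physiology$flows_l_h
  q[["gut"]] + q[["spleen"]] + q[["pancreas"]] + q[["hepatic_artery"]]
}
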