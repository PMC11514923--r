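#' Digital phantom specification
#'
#' Parameters of the schematic brain phantom used to exercise the full
#' pipeline: grid geometry, per-tissue baseline T1, contrast-agent relaxivity,
#' vascular gadolinium concentrations at the two post-injection sessions,
#' per-region leakage fractions representing blood-brain barrier dysfunction
#' (BBBD), voxel noise and session-to-session rigid misalignment.
#'
#' BBBD is parameterized as a leakage fraction `lambda` in [0, 1]: the
#' parenchymal gadolinium concentration of a region is `lambda` times the
#' concurrent vascular concentration. This is the simplest mechanism giving
#' the observable of interest, a local T1 reduction proportional to leaked
#' tracer; full pharmacokinetic (Tofts) modelling is deliberately out of
#' scope.
#'
#' Baseline T1 values are typical 3 T tissue values (ms). The default
#' relaxivity 5 L mmol^-1 s^-1 is the literature value for gadobutrol at 3 T.
#' Vascular concentration at scan time is a free parameter (dilution and
#' kinetics make it unknowable from the injected dose); the interictal and
#' postictal values are independent to emulate injection-to-scan latency
#' variability.
#'
#' @param shape grid shape in voxels, default `c(64, 64, 64)` at 1 mm
#'   isotropic.
#' @param voxel_mm isotropic voxel size in mm.
#' @param t1_tissues named numeric vector of baseline T1 (ms) for `cortex`,
#'   `white_matter`, `csf`, `hippocampus`, `amygdala`, `piriform`, `blood`.
#' @param r1 contrast-agent relaxivity in L mmol^-1 s^-1.
#' @param c_vasc_ii,c_vasc_pi vascular gadolinium concentration (mmol/L) at
#'   the interictal and postictal scans.
#' @param leakage named list of per-session leakage fractions: elements
#'   `interictal` and `postictal`, each a named numeric vector over
#'   parenchymal region names (e.g. `piriform_l`); missing regions leak 0.
#' @param noise_sd voxel noise as a fraction of the local T1 value (0.01 =
#'   1\%).
#' @param motion_mm,motion_deg magnitude bounds of the random rigid
#'   perturbation applied to each post-contrast session.
#' @param pv_sigma Gaussian partial-volume width (voxels) of the rendering:
#'   emulates the acquisition point-spread function, so tissue boundaries
#'   carry realistic mixed-intensity voxels instead of step edges (0 renders
#'   crisp labels). Interior voxels keep exactly the tissue T1.
#' @param seed integer random seed; fixed seed gives bit-identical output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), voxel_mm = 1,
                         t1_tissues = c(cortex = 1300, white_matter = 850,
                                        csf = 4000, hippocampus = 1350,
                                        amygdala = 1300, piriform = 1300,
                                        blood = 1650),
                         r1 = 5, c_vasc_ii = 0.5, c_vasc_pi = 0.6,
                         leakage = list(interictal = c(), postictal = c()),
                         noise_sd = 0.01, motion_mm = 2, motion_deg = 2,
                         pv_sigma = 0.6, seed = 1L) {
  if (any(shape < 32)) stop("grid too small to host all phantom regions (need >= 32 voxels per axis)")
  need <- c("cortex", "white_matter", "csf", "hippocampus", "amygdala",
            "piriform", "blood")
  if (!all(need %in% names(t1_tissues))) stop("t1_tissues must name: ",
                                              paste(need, collapse = ", "))
  if (any(t1_tissues <= 0)) stop("all tissue T1 values must be positive")
  if (r1 <= 0) stop("relaxivity must be positive")
  if (c_vasc_ii < 0 || c_vasc_pi < 0) stop("vascular concentrations must be >= 0")
  lk <- lapply(c(interictal = "interictal", postictal = "postictal"),
               function(s) {
                 v <- leakage[[s]]
                 if (length(v) && (any(v < 0) || any(v > 1)))
                   stop("leakage fractions must lie in [0, 1]")
                 v
               })
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 t1_tissues = t1_tissues, r1 = r1,
                 c_vasc_ii = c_vasc_ii, c_vasc_pi = c_vasc_pi,
                 leakage = lk, noise_sd = noise_sd,
                 motion_mm = motion_mm, motion_deg = motion_deg,
                 pv_sigma = pv_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# standard label dictionary of the phantom
phantom_label_dict <- function() {
  c(cortex = 1L, white_matter = 2L, csf = 3L,
    hippocampus_l = 11L, hippocampus_r = 12L,
    amygdala_l = 21L, amygdala_r = 22L,
    piriform_l = 31L, piriform_r = 32L,
    sss = 40L)
}

#' Parenchymal (non-vascular, non-support) region names of the phantom
#' @return character vector of the bilateral deep-structure region names.
#' @export
parenchymal_rois <- function() {
  c("hippocampus_l", "hippocampus_r", "amygdala_l", "amygdala_r",
    "piriform_l", "piriform_r")
}

tissue_of_label <- function() {
  c(cortex = "cortex", white_matter = "white_matter", csf = "csf",
    hippocampus_l = "hippocampus", hippocampus_r = "hippocampus",
    amygdala_l = "amygdala", amygdala_r = "amygdala",
    piriform_l = "piriform", piriform_r = "piriform",
    sss = "blood")
}

#' Build the schematic phantom: label map and baseline qT1 volume
#'
#' The geometry is deliberately schematic, not anatomical: an ellipsoidal
#' brain whose outer shell is cortex around a white-matter interior (their
#' interface carries a fixed sinusoidal folding pattern), central CSF;
#' bilateral ellipsoidal hippocampus, amygdala and piriform cortex blobs in
#' the deep temporal region; and a superior sagittal sinus (SSS) segment
#' restricted to three consecutive coronal slices at the superior midline,
#' mirroring how the vascular reference ROI is delineated in practice.
#' Region identity and adjacency, not shape fidelity, drive the downstream
#' analysis. Rendering applies Gaussian partial-volume smoothing of width
#' `spec$pv_sigma` to the T1 map (see [phantom_spec()]).
#'
#' @param spec a [phantom_spec()].
#' @return list with `labels` (an [roi_label_map()]) and `t1` (the baseline,
#'   noiseless [qt1_volume()], valid over the whole head including SSS).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  ren <- render_phantom(spec)
  counts <- vapply(ren$labels$dict, function(v) sum(ren$labels$labels == v),
                   integer(1))
  if (any(counts < 30))
    stop("grid too small to host all phantom regions (smallest: ",
         names(which.min(counts)), " = ", min(counts), " voxels)")
  ren
}

# Evaluate the phantom's region membership at arbitrary continuous
# coordinates (n x 3 matrix, voxel units, 0-based). Analytic evaluation is
# what lets a session be rendered directly on a rigidly moved grid — a moved
# head is re-acquired by the scanner, not interpolated from another image.
phantom_labels_at <- function(spec, coords) {
  d <- spec$shape
  ctr <- (d - 1) / 2
  sc <- d / 64                                     # scale geometry with grid
  dict <- phantom_label_dict()
  lab <- integer(nrow(coords))

  cx <- coords[, 1] - ctr[1]
  cy <- coords[, 2] - ctr[2]
  cz <- coords[, 3] - ctr[3]

  dx <- cx / (24 * sc[1]); dy <- cy / (28 * sc[2]); dz <- cz / (22 * sc[3])
  rho2 <- dx^2 + dy^2 + dz^2
  brain <- rho2 <= 1
  # cortex-white-matter interface carries schematic folding: a fixed angular
  # modulation of the interface radius. Besides being what cortex looks like,
  # the folding breaks the rotational near-symmetry of a smooth shell, which
  # is what anchors intensity-based rigid registration in real data too.
  theta <- atan2(dy, dx)
  phi <- atan2(dz, sqrt(dx^2 + dy^2))
  fold <- 1 + 0.06 * sin(4 * theta) * cos(3 * phi) +
              0.05 * cos(3 * theta + 1) * sin(2 * phi + 0.5)
  inner <- sqrt(rho2) <= 0.82 * fold
  lab[brain] <- dict[["cortex"]]
  lab[brain & inner] <- dict[["white_matter"]]

  inside <- function(offset, radii) {
    ((cx - offset[1] * sc[1]) / (radii[1] * sc[1]))^2 +
      ((cy - offset[2] * sc[2]) / (radii[2] * sc[2]))^2 +
      ((cz - offset[3] * sc[3]) / (radii[3] * sc[3]))^2 <= 1
  }
  lab[inside(c(0, -2, 2), c(5, 8, 4))] <- dict[["csf"]]
  lab[inside(c(-14, -6, -4), c(4, 6, 3.5))] <- dict[["hippocampus_l"]]
  lab[inside(c( 14, -6, -4), c(4, 6, 3.5))] <- dict[["hippocampus_r"]]
  lab[inside(c(-14,  3, -5), c(3.2, 3.2, 3))] <- dict[["amygdala_l"]]
  lab[inside(c( 14,  3, -5), c(3.2, 3.2, 3))] <- dict[["amygdala_r"]]
  lab[inside(c(-17,  7, -9), c(3, 3.2, 2.6))] <- dict[["piriform_l"]]
  lab[inside(c( 17,  7, -9), c(3, 3.2, 2.6))] <- dict[["piriform_r"]]

  # SSS: midline tube at the top of the brain, spanning exactly 3
  # consecutive coronal slices of the unmoved grid
  y0 <- round(ctr[2])
  sss <- abs(cx) <= 2 * sc[1] &
    coords[, 2] > y0 - 0.5 & coords[, 2] < y0 + 2.5 &
    abs(cz - 20 * sc[3]) <= 2 * sc[3]
  lab[sss] <- dict[["sss"]]
  lab
}

# Render the phantom on its grid, optionally through a rigid transform
# (the rendered image I satisfies I(x) = phantom(transform(x))). The crisp
# per-tissue T1 assignment is followed by Gaussian partial-volume smoothing
# of width spec$pv_sigma, emulating the acquisition point-spread function;
# interior voxels keep exactly the tissue T1.
render_phantom <- function(spec, transform = NULL) {
  d <- spec$shape
  aff <- diag(c(rep(spec$voxel_mm, 3), 1))
  ijk <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  coords <- ijk
  if (!is.null(transform)) {
    m <- transform_matrix(transform)
    xyz <- sweep(ijk * spec$voxel_mm, 2, 0, "+")        # world = voxel * mm
    xyz <- sweep(xyz %*% t(m[1:3, 1:3]), 2, m[1:3, 4], "+")
    coords <- xyz / spec$voxel_mm
  }
  lab <- array(phantom_labels_at(spec, coords), d)

  t1 <- array(0, d)
  dict <- phantom_label_dict()
  tofl <- tissue_of_label()
  for (nm in names(dict)) t1[lab == dict[[nm]]] <- spec$t1_tissues[[tofl[[nm]]]]
  vol <- qt1_volume(t1, affine = aff, session = "noncontrast", mask = lab > 0L)
  if (spec$pv_sigma > 0) vol <- gaussian_smooth(vol, spec$pv_sigma)
  list(labels = roi_label_map(lab, dict = dict, affine = aff), t1 = vol)
}

#' Apply gadolinium contrast to a T1 map
#'
#' Fast-exchange relaxivity model: the post-contrast longitudinal relaxation
#' rate is \eqn{1/T_{1,post} = 1/T_{1,pre} + r_1 C} with relaxivity `r1` in
#' L mmol^-1 s^-1 and concentration map `concentration` in mmol/L (r1 is
#' converted internally to per-ms units). Gadolinium can only shorten T1:
#' the output is voxelwise no greater than the input and strictly decreasing
#' in concentration.
#'
#' @param t1_pre a [qt1_volume()].
#' @param concentration 3-D array of gadolinium concentration (mmol/L), same
#'   shape, non-negative.
#' @param r1 relaxivity in L mmol^-1 s^-1 (default 5, gadobutrol at 3 T).
#' @param session session label for the returned volume.
#' @return a [qt1_volume()] with shortened T1.
#' @export
apply_contrast <- function(t1_pre, concentration, r1 = 5,
                           session = "interictal") {
  stopifnot(inherits(t1_pre, "qt1_volume"))
  if (!identical(dim(concentration), dim(t1_pre$t1)))
    stop("concentration map must match the T1 map shape")
  if (any(concentration < 0, na.rm = TRUE))
    stop("concentration must be non-negative everywhere")
  r1_ms <- r1 / 1000                                  # per mM per ms
  t1 <- t1_pre$t1
  v <- t1_pre$mask & concentration > 0        # zero dose is the exact identity
  t1[v] <- 1 / (1 / t1[v] + r1_ms * concentration[v])
  qt1_volume(t1, affine = t1_pre$affine, session = session, mask = t1_pre$mask)
}

# Per-session concentration map: vascular concentration in the SSS, leakage
# fraction times vascular concentration in the named parenchymal regions.
concentration_map <- function(labels, c_vasc, leakage) {
  conc <- array(0, dim(labels$labels))
  conc[roi_mask(labels, "sss")] <- c_vasc
  if (length(leakage)) {
    for (nm in names(leakage)) {
      if (!nm %in% names(labels$dict)) stop("unknown leakage region: ", nm)
      conc[roi_mask(labels, nm)] <- leakage[[nm]] * c_vasc
    }
  }
  conc
}

random_rigid <- function(spec, center) {
  rigid_transform(rotation = stats::runif(3, -spec$motion_deg, spec$motion_deg),
                  translation = stats::runif(3, -spec$motion_mm, spec$motion_mm),
                  center = center)
}

apply_t1_noise <- function(vol, noise_sd) {
  if (noise_sd <= 0) return(vol)
  t1 <- vol$t1
  t1[vol$mask] <- t1[vol$mask] *
    (1 + stats::rnorm(sum(vol$mask), 0, noise_sd))
  t1[vol$mask] <- pmax(t1[vol$mask], 1)
  qt1_volume(t1, affine = vol$affine, session = vol$session, mask = vol$mask)
}

#' Simulate the three qT1 sessions of one phantom subject
#'
#' Produces the noncontrast, interictal post-contrast and postictal
#' post-contrast qT1 volumes of one subject: the baseline phantom, and two
#' contrasted versions carrying vascular gadolinium in the SSS plus
#' region-specific parenchymal leakage, each perturbed by a random rigid
#' transform (subject repositioning between sessions) and voxel noise.
#' Ground truth records the noiseless, unperturbed per-region mean
#' subtraction values, both raw (ms) and normalized by the SSS mean.
#'
#' With `emit_vfa = TRUE` the function additionally returns raw variable
#' flip angle signal series per session (forward-modelled from the noiseless
#' aligned T1 maps before motion), so the relaxometry fit can be exercised
#' in-pipeline.
#'
#' @param spec a [phantom_spec()].
#' @param emit_vfa also return `vfa` (list of [vfa_series()] per session).
#' @param acq acquisition used when `emit_vfa = TRUE`.
#' @return list with `sessions` (named list of three [qt1_volume()]),
#'   `labels`, `truth` (data.frame: roi, delta_ni, delta_ip, norm_ni,
#'   norm_ip), `motion` (applied [rigid_transform()] per post-contrast
#'   session) and optionally `vfa`.
#' @export
simulate_sessions <- function(spec = phantom_spec(), emit_vfa = FALSE,
                              acq = acquisition_params()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  ph <- make_phantom(spec)
  labels <- ph$labels
  base <- ph$t1

  conc_ii <- concentration_map(labels, spec$c_vasc_ii, spec$leakage$interictal)
  conc_pi <- concentration_map(labels, spec$c_vasc_pi, spec$leakage$postictal)
  ii_clean <- apply_contrast(base, conc_ii, r1 = spec$r1, session = "interictal")
  pi_clean <- apply_contrast(base, conc_pi, r1 = spec$r1, session = "postictal")

  truth <- session_truth(base, ii_clean, pi_clean, labels)

  center <- volume_center_world(base)
  mo_ii <- random_rigid(spec, center)
  mo_pi <- random_rigid(spec, center)
  # moved sessions are re-rendered analytically on the perturbed grid (the
  # scanner re-acquires a moved head; it does not interpolate an image)
  moved_session <- function(motion, c_vasc, leakage, session) {
    if (max(abs(transform_matrix(motion) - diag(4))) < 1e-12) {
      ren <- list(labels = labels, t1 = base)
    } else {
      ren <- render_phantom(spec, transform = motion)
    }
    conc <- concentration_map(ren$labels, c_vasc, leakage)
    apply_contrast(ren$t1, conc, r1 = spec$r1, session = session)
  }
  nc <- apply_t1_noise(base, spec$noise_sd)
  ii <- apply_t1_noise(moved_session(mo_ii, spec$c_vasc_ii,
                                     spec$leakage$interictal, "interictal"),
                       spec$noise_sd)
  pi_ <- apply_t1_noise(moved_session(mo_pi, spec$c_vasc_pi,
                                      spec$leakage$postictal, "postictal"),
                        spec$noise_sd)

  out <- list(sessions = list(noncontrast = nc, interictal = ii, postictal = pi_),
              labels = labels, truth = truth,
              motion = list(interictal = mo_ii, postictal = mo_pi))
  if (emit_vfa) {
    out$vfa <- list(
      noncontrast = simulate_vfa(base, acq, noise_sd = spec$noise_sd * 0.1),
      interictal = simulate_vfa(ii_clean, acq, noise_sd = spec$noise_sd * 0.1),
      postictal = simulate_vfa(pi_clean, acq, noise_sd = spec$noise_sd * 0.1))
  }
  out
}

# Noiseless, motion-free per-ROI ground truth of the subtraction biomarkers.
session_truth <- function(base, ii_clean, pi_clean, labels) {
  d_ni <- base$t1 - ii_clean$t1
  d_ip <- ii_clean$t1 - pi_clean$t1
  sssm <- roi_mask(labels, "sss")
  sss_ni <- mean(d_ni[sssm]); sss_ip <- mean(d_ip[sssm])
  rois <- c("cortex", parenchymal_rois(), "sss")
  rows <- lapply(rois, function(nm) {
    m <- roi_mask(labels, nm)
    data.frame(roi = nm,
               delta_ni = mean(d_ni[m]), delta_ip = mean(d_ip[m]),
               norm_ni = if (sss_ni != 0) mean(d_ni[m]) / sss_ni else NA_real_,
               norm_ip = if (sss_ip != 0) mean(d_ip[m]) / sss_ip else NA_real_)
  })
  do.call(rbind, rows)
}
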