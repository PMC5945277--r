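#' Toy potentials with analytically known free-energy profiles
#'
#' Two forms: `"harmonic"` — U(z) = 1/2 stiffness (z - center)^2 — and
#' `"quartic_double_well"` — U(z) = barrier_h (((z - center)/width_w)^2 - 1)^2,
#' a symmetric double well with minima at center +- width_w and a barrier
#' of height barrier_h at the center. All energies in kT, coordinates in
#' nm.
#'
#' @param form `"harmonic"` or `"quartic_double_well"`.
#' @param barrier_h barrier height (kT) of the double well.
#' @param width_w half-separation of the double-well minima (nm).
#' @param center potential center (nm).
#' @param stiffness harmonic stiffness (kT/nm^2).
#' @return an object of class `toy_potential` (callable via
#'   [potential_energy]).
#' @export
toy_potential <- function(form = c("harmonic", "quartic_double_well"),
                          barrier_h = 5, width_w = 1, center = 0,
                          stiffness = 1) {
  form <- match.arg(form)
  if (form == "quartic_double_well" && barrier_h <= 0)
    stop_input("barrier_h must be > 0 for the double well")
  if (width_w <= 0) stop_input("width_w must be > 0")
  structure(list(form = form, barrier_h = barrier_h, width_w = width_w,
                 center = center, stiffness = stiffness),
            class = "toy_potential")
}

#' Evaluate a toy potential
#'
#' @param potential a [toy_potential].
#' @param z coordinate value(s) (nm).
#' @return potential energy in kT (vectorized).
#' @export
potential_energy <- function(potential, z) {
  zc <- z - potential$center
  switch(potential$form,
    harmonic = 0.5 * potential$stiffness * zc^2,
    quartic_double_well =
      potential$barrier_h * ((zc / potential$width_w)^2 - 1)^2)
}

#' Analytic free-energy profile of a toy potential
#'
#' Ground truth for WHAM validation: G(z) = U(z) - min U on the bin grid,
#' with zero error.
#'
#' @param potential a [toy_potential].
#' @param bins bin centers (numeric vector) or a bin count over
#'   `range` (default 100 bins over center +- 2 width_w).
#' @param range coordinate range when `bins` is a count.
#' @return a `free_energy_profile`.
#' @export
analytic_pmf <- function(potential, bins = 100, range = NULL) {
  centers <- if (length(bins) > 1) bins else {
    r <- range %||% (potential$center + c(-2, 2) * potential$width_w)
    mids(seq(r[1], r[2], length.out = bins + 1))
  }
  U <- potential_energy(potential, centers)
  free_energy_profile(centers, U - min(U))
}

#' Two multivariate-Gaussian ensembles separated along a planted direction
#'
#' Generates two flat ensembles with means at +-(gap/2) along a planted
#' unit separation vector and a shared diagonal covariance (in the
#' coordinate axes), emulating a pair of non-overlapping simulated
#' conformational ensembles. Ground truth for the separation search.
#'
#' @param dim coordinate dimension (3N).
#' @param n_frames frames per ensemble.
#' @param separation_vector unit `dim`-vector (default the first coordinate
#'   axis); normalized if needed.
#' @param gap distance between the two ensemble means (nm).
#' @param covariance diagonal covariance spectrum: a scalar (isotropic) or
#'   a length-`dim` vector of variances (nm^2).
#' @param seed RNG seed.
#' @return list with `ens1`, `ens2` ([flat_ensemble]s) and
#'   `separation_vector`.
#' @export
gen_two_gaussian_ensembles <- function(dim, n_frames, separation_vector = NULL,
                                       gap = 8, covariance = 1, seed = 1) {
  if (gap < 0) stop_input("gap must be >= 0")
  v <- separation_vector %||% c(1, rep(0, dim - 1))
  v <- v / sqrt(sum(v^2))
  sd_vec <- sqrt(if (length(covariance) == 1) rep(covariance, dim) else covariance)
  set.seed(seed)
  draw <- function(center) {
    X <- matrix(stats::rnorm(n_frames * dim), n_frames, dim)
    X <- sweep(X, 2, sd_vec, `*`)
    sweep(X, 2, center, `+`)
  }
  list(ens1 = flat_ensemble(draw(+gap / 2 * v)),
       ens2 = flat_ensemble(draw(-gap / 2 * v)),
       separation_vector = v)
}

#' Hinge-dimer bead model with Boltzmann-distributed bending
#'
#' Builds a two-arm bead model joined at a hinge: arm A lies along the -x
#' axis, arm B starts along +x and is rotated in the x-y plane by a
#' per-frame bending angle theta drawn from the Boltzmann distribution of
#' the harmonic hinge potential 1/2 kappa (theta - theta0)^2 (variance
#' 1/kappa in kT units). With probability `p_state` the whole B arm is
#' additionally displaced by `anchor_shift` along z — a second discrete
#' "anchor" state whose separating direction is, by construction,
#' orthogonal to the in-plane bending motion. I.i.d. Gaussian jitter is
#' added to every bead. Frames are built in a common lab frame, so the
#' ensemble is already superposed.
#'
#' @param n_beads_per_arm beads per arm (>= 2).
#' @param hinge_stiffness kappa in kT/rad^2.
#' @param theta0 mean bending angle (rad).
#' @param anchor_shift z-displacement of the second anchor state (nm).
#' @param p_state probability of the shifted state.
#' @param n_frames number of frames.
#' @param noise_sigma per-coordinate jitter SD (nm).
#' @param bond_length bead spacing (nm).
#' @param seed RNG seed.
#' @return a [structure_ensemble] with attributes `theta` (per-frame
#'   bending angle), `anchor_state` (1 or 2 per frame) and `bend_direction`
#'   (unit 3N vector: the planted bending displacement pattern at theta0).
#' @export
gen_hinge_dimer <- function(n_beads_per_arm = 10, hinge_stiffness = 10,
                            theta0 = 0.3, anchor_shift = 0, p_state = 0,
                            n_frames = 1000, noise_sigma = 0.01,
                            bond_length = 0.4, seed = 1) {
  if (n_beads_per_arm < 2) stop_input("need >= 2 beads per arm")
  nb <- n_beads_per_arm
  set.seed(seed)
  theta <- stats::rnorm(n_frames, theta0, sqrt(1 / hinge_stiffness))
  state <- 1L + (stats::runif(n_frames) < p_state)
  arm_r <- bond_length * seq_len(nb)
  n_at <- 2 * nb + 1          # arm A, hinge bead, arm B
  coords <- array(0, c(n_frames, n_at, 3))
  for (f in seq_len(n_frames)) {
    xyz <- matrix(0, n_at, 3)
    xyz[seq_len(nb), 1] <- -rev(arm_r)                     # arm A on -x
    xyz[nb + 1, ] <- 0                                      # hinge
    bi <- nb + 1 + seq_len(nb)
    xyz[bi, 1] <- arm_r * cos(theta[f])
    xyz[bi, 2] <- arm_r * sin(theta[f])
    if (state[f] == 2L) xyz[bi, 3] <- xyz[bi, 3] + anchor_shift
    coords[f, , ] <- xyz + matrix(stats::rnorm(n_at * 3, 0, noise_sigma),
                                  n_at, 3)
  }
  ens <- structure_ensemble(coords,
                            frame_labels = sprintf("frame%04d", seq_len(n_frames)))
  # planted bending displacement at theta0: d(xyz)/d(theta) for arm B
  bend <- matrix(0, n_at, 3)
  bend[nb + 1 + seq_len(nb), 1] <- -arm_r * sin(theta0)
  bend[nb + 1 + seq_len(nb), 2] <- arm_r * cos(theta0)
  bend_flat <- as.vector(t(bend))
  attr(ens, "theta") <- theta
  attr(ens, "anchor_state") <- state
  attr(ens, "bend_direction") <- bend_flat / sqrt(sum(bend_flat^2))
  ens
}

#' Metropolis-sampled umbrella windows on a toy potential
#'
#' Samples each window's reaction coordinate by Metropolis Monte Carlo on
#' U(z) + 1/2 k (z - center)^2 (energies in kT; the spring constant is
#' given in kJ mol^-1 nm^-2 and converted at `temperature`). Metropolis
#' sampling has the exact stationary distribution, so the recovered
#' profiles can be compared against [analytic_pmf] without integrator
#' bias.
#'
#' @param potential a [toy_potential].
#' @param centers window bias positions (nm).
#' @param spring_k spring constant, kJ mol^-1 nm^-2 (scalar or per
#'   window).
#' @param n_steps Monte Carlo steps per window.
#' @param step_size proposal half-width (nm).
#' @param discard initial samples dropped as equilibration.
#' @param temperature Kelvin.
#' @param seed RNG seed.
#' @return list of [umbrella_window]s; each carries attributes
#'   `acceptance_rate` and `potential`.
#' @export
gen_umbrella_windows <- function(potential, centers, spring_k = 100,
                                 n_steps = 20000, step_size = 0.2,
                                 discard = 1000, temperature = 300,
                                 seed = 1) {
  if (length(centers) == 0) stop_input("centers must be non-empty")
  if (n_steps <= discard) stop_input("n_steps must exceed discard")
  kT <- kT_kJmol(temperature)
  spring_k <- rep(spring_k, length.out = length(centers))
  set.seed(seed)
  win_seeds <- sample.int(2147483646L, length(centers))
  out <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    set.seed(win_seeds[i])
    k_kT <- spring_k[i] / kT
    u_tot <- function(z) potential_energy(potential, z) +
      0.5 * k_kT * (z - centers[i])^2
    z <- centers[i]
    uz <- u_tot(z)
    series <- numeric(n_steps)
    acc <- 0L
    prop <- stats::runif(n_steps, -step_size, step_size)
    unif <- stats::runif(n_steps)
    for (s in seq_len(n_steps)) {
      zn <- z + prop[s]
      un <- u_tot(zn)
      if (unif[s] < exp(uz - un)) { z <- zn; uz <- un; acc <- acc + 1L }
      series[s] <- z
    }
    rate <- acc / n_steps
    if (rate < 0.01)
      stop_input("acceptance rate below 1% in window at ", centers[i],
                 "; reduce step_size")
    w <- umbrella_window(centers[i], spring_k[i], series, discard = discard,
                         zero_bias = all(spring_k[i] == 0))
    attr(w, "acceptance_rate") <- rate
    attr(w, "potential") <- potential
    out[[i]] <- w
  }
  out
}

#' Write a deterministic fixture bundle
#'
#' Generates and writes the synthetic inputs used by the documentation and
#' end-to-end tests: a planted two-Gaussian ensemble pair (delimited
#' text), a hinge-dimer ensemble (multi-model PDB plus a frame-label
#' table), umbrella-window series files and a manifest recording every
#' file with its generator parameters. Deterministic under
#' `master_seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param master_seed integer master seed; per-generator sub-seeds are
#'   derived from it.
#' @return the manifest (a list), invisibly written as
#'   `manifest.yaml` in `out_dir`.
#' @export
write_fixture_set <- function(out_dir, master_seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(master_seed = master_seed, files = list())
  add <- function(manifest, name, params) {
    manifest$files[[name]] <- params
    manifest
  }

  gg <- gen_two_gaussian_ensembles(dim = 12, n_frames = 300, gap = 6,
                                   seed = derive_seed(master_seed, 1))
  write_flat_ensemble(gg$ens1, file.path(out_dir, "gauss_ens1.tsv"))
  write_flat_ensemble(gg$ens2, file.path(out_dir, "gauss_ens2.tsv"))
  manifest <- add(manifest, "gauss_ens1.tsv",
                  list(generator = "gen_two_gaussian_ensembles", dim = 12,
                       n_frames = 300, gap = 6,
                       seed = derive_seed(master_seed, 1)))
  manifest <- add(manifest, "gauss_ens2.tsv",
                  manifest$files[["gauss_ens1.tsv"]])

  hd <- gen_hinge_dimer(n_beads_per_arm = 6, n_frames = 60,
                        anchor_shift = 0.5, p_state = 0.5,
                        seed = derive_seed(master_seed, 2))
  write_pdb_ensemble(hd, file.path(out_dir, "hinge_dimer.pdb"))
  utils::write.table(
    data.frame(frame = hd$frame_labels, theta = attr(hd, "theta"),
               anchor_state = attr(hd, "anchor_state")),
    file.path(out_dir, "hinge_dimer_labels.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- add(manifest, "hinge_dimer.pdb",
                  list(generator = "gen_hinge_dimer", n_beads_per_arm = 6,
                       n_frames = 60, anchor_shift = 0.5, p_state = 0.5,
                       seed = derive_seed(master_seed, 2)))

  pot <- toy_potential("quartic_double_well", barrier_h = 5, width_w = 1)
  wins <- gen_umbrella_windows(pot, centers = seq(-1.6, 1.6, length.out = 11),
                               spring_k = 100, n_steps = 4000, discard = 500,
                               seed = derive_seed(master_seed, 3))
  write_windows(wins, out_dir, prefix = "window")
  manifest <- add(manifest, "window_manifest.tsv",
                  list(generator = "gen_umbrella_windows",
                       potential = "quartic_double_well", barrier_h = 5,
                       width_w = 1, n_windows = 11, spring_k = 100,
                       n_steps = 4000, discard = 500,
                       seed = derive_seed(master_seed, 3)))

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Write / read umbrella windows as delimited text plus a manifest
#'
#' One two-column file (`step`, `z`) per window and a manifest table
#' listing file, bias center, spring constant and discard span — the
#' layout common WHAM tools consume.
#'
#' @param windows list of [umbrella_window]s.
#' @param dir directory.
#' @param prefix file-name prefix.
#' @export
write_windows <- function(windows, dir, prefix = "window") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    fn <- sprintf("%s_%02d.tsv", prefix, i)
    utils::write.table(data.frame(step = seq_along(w$series), z = w$series),
                       file.path(dir, fn), sep = "\t", row.names = FALSE,
                       quote = FALSE)
    data.frame(file = fn, center = w$center, spring_k = w$spring_k,
               discard = w$discard)
  })
  utils::write.table(do.call(rbind, rows),
                     file.path(dir, paste0(prefix, "_manifest.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_windows
#' @param manifest_path path to the `*_manifest.tsv` file.
#' @export
read_windows <- function(manifest_path) {
  man <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  dir <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    df <- utils::read.table(file.path(dir, man$file[i]), header = TRUE,
                            sep = "\t")
    umbrella_window(man$center[i], man$spring_k[i], df$z,
                    discard = man$discard[i],
                    zero_bias = man$spring_k[i] == 0)
  })
}
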