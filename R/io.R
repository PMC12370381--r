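#' Write a structure set to the package's JSON exchange format
#'
#' Structures are serialised as named lists of contours (slice position z in
#' mm plus the vertex list in patient coordinates, mm), with the frame of
#' reference and nominal slice thickness — the same information content as
#' an RT Structure Set's contour data. Round-trips exactly through
#' [read_structures_json()].
#'
#' @param sset a [structure_set()] (or a single [rt_structure()]).
#' @param path output file path.
#' @export
write_structures_json <- function(sset, path) {
  if (inherits(sset, "rt_structure")) sset <- structure_set(list(sset))
  payload <- list(
    frame_of_reference = sset$frame_of_reference,
    structures = lapply(sset$structures, function(s) list(
      name = s$name, st = s$st, analytic = s$analytic,
      contours = lapply(s$contours, function(cc)
        list(z = cc$z, vertices = cc$vertices)))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a structure set from the JSON exchange format
#' @param path file path produced by [write_structures_json()].
#' @return a [structure_set()].
#' @export
read_structures_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  structs <- lapply(p$structures, function(s) {
    analytic <- s$analytic
    if (!length(analytic)) analytic <- NULL
    if (!is.null(analytic)) {
      a <- list(type = as.character(analytic$type),
                center = as.numeric(unlist(analytic$center)),
                radius = as.numeric(analytic$radius),
                n_vertices = as.integer(analytic$n_vertices),
                phase = as.numeric(analytic$phase))
      if (!is.null(analytic$harmonics))
        a$harmonics <- list(
          k = as.integer(unlist(analytic$harmonics$k)),
          a = as.numeric(unlist(analytic$harmonics$a)),
          psi = as.numeric(unlist(analytic$harmonics$psi)))
      analytic <- a
    }
    rt_structure(
      s$name,
      lapply(s$contours, function(cc)
        planar_contour(cc$z, do.call(rbind, lapply(cc$vertices, unlist)))),
      st = s$st, analytic = analytic)
  })
  structure_set(structs, frame_of_reference = p$frame_of_reference)
}

#' Write a phantom bundle as a plain-text case directory
#'
#' Serialises a bundle the way the package exchanges cases on disk:
#' `geometry.json` (CT lattice, dose-grid resolution, prescription, seeds,
#' per-target dose models and evaluation regions), `structures.json`
#' (contours in patient coordinates, mm) and `manifest.csv` (closed-form
#' nominal values). Optionally materialises each target's dose matrix as a
#' CSV of voxel values with its lattice header. The layout is re-read by
#' [read_bundle()] with round-trip equality of geometry, contours and dose.
#'
#' @param bundle a `phantom_bundle`.
#' @param dir output directory (created if needed).
#' @param dose_matrices also write materialised per-target dose matrices.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, dose_matrices = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- list(
    kind = bundle$kind,
    ct_grid = bundle$ct_grid[c("origin", "spacing", "dims")],
    dose_spacing = bundle$dose_spacing,
    prescription = bundle$prescription,
    seed = bundle$seed,
    bath_field = bundle$bath_field,
    targets = lapply(bundle$targets, function(t) list(
      name = t$structure$name, diameter = t$diameter,
      model = unclass(t$model),
      region = t$region[c("type", "center", "radius", "name")])))
  jsonlite::write_json(geom, file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  write_structures_json(structure_set(lapply(bundle$targets, `[[`, "structure")),
                        file.path(dir, "structures.json"))
  utils::write.csv(bundle$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (dose_matrices) {
    for (i in seq_along(bundle$targets)) {
      d <- target_dose(bundle, i)
      con <- file.path(dir, sprintf("dose_%03d.csv", i))
      hdr <- sprintf("# origin %s spacing %s dims %s prescription %g",
                     paste(d$grid$origin, collapse = ","),
                     paste(d$grid$spacing, collapse = ","),
                     paste(d$grid$dims, collapse = ","),
                     d$prescription)
      writeLines(hdr, con)
      utils::write.table(matrix(as.numeric(d$values), nrow = 1),
                         con, append = TRUE, row.names = FALSE,
                         col.names = FALSE, sep = ",")
    }
  }
  invisible(dir)
}

#' Read a case directory written by [write_bundle()]
#' @param dir the case directory.
#' @return a `phantom_bundle`.
#' @export
read_bundle <- function(dir) {
  gpath <- file.path(dir, "geometry.json")
  if (!file.exists(gpath)) stop(sprintf("no geometry.json under '%s'", dir))
  geom <- jsonlite::read_json(gpath, simplifyVector = FALSE)
  sset <- read_structures_json(file.path(dir, "structures.json"))
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  targets <- vector("list", length(geom$targets))
  for (i in seq_along(targets)) {
    tg <- geom$targets[[i]]
    m <- tg$model
    model <- dose_model(R = m$R, g = m$g, plateau = m$plateau,
                        bath = m$bath, peak_ratio = m$peak_ratio,
                        scales = as.numeric(unlist(m$scales)),
                        center = as.numeric(unlist(m$center)))
    region <- eval_region_sphere(as.numeric(unlist(tg$region$center)),
                                 tg$region$radius, name = tg$region$name)
    targets[[i]] <- list(structure = sset$structures[[tg$name]],
                         model = model, region = region,
                         diameter = tg$diameter)
  }
  out <- list(kind = geom$kind,
              ct_grid = voxel_grid(unlist(geom$ct_grid$origin),
                                   unlist(geom$ct_grid$spacing),
                                   unlist(geom$ct_grid$dims)),
              dose_spacing = as.numeric(unlist(geom$dose_spacing)),
              targets = targets, manifest = manifest,
              prescription = geom$prescription, seed = geom$seed)
  if (length(geom$bath_field))
    out$bath_field <- list(level = geom$bath_field$level,
                           center = as.numeric(unlist(geom$bath_field$center)),
                           sigma = geom$bath_field$sigma)
  structure(out, class = "phantom_bundle")
}

#' Read a materialised dose matrix written by [write_bundle()]
#' @param path a `dose_*.csv` file.
#' @return a [dose_grid()].
#' @export
read_dose_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  f <- regmatches(hdr, gregexpr("-?[0-9.]+", hdr))[[1]]
  f <- as.numeric(f)
  origin <- f[1:3]; spacing <- f[4:6]; dims <- as.integer(f[7:9]); rx <- f[10]
  vals <- as.numeric(utils::read.table(path, skip = 1, sep = ",")[1, ])
  dose_grid(voxel_grid(origin, spacing, dims), array(vals, dims), rx)
}

#' Export a DVH curve as CSV (dose %, cm^3, %)
#' @param curve a `dvh_curve`; @param path output path.
#' @export
write_dvh_csv <- function(curve, path) {
  utils::write.csv(data.frame(dose_pct = curve$dose, volume_cm3 = curve$cum_cm3,
                              volume_pct = curve$cum_pct),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export study records and statistics
#'
#' Writes `records.csv` (one row per target x quantity x perturbation),
#' `index_stats.csv` and `ratio_fits.json` under `dir`.
#'
#' @param study a `study_result`; @param dir output directory.
#' @export
write_study_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$records, file.path(dir, "records.csv"), row.names = FALSE)
  utils::write.csv(study$index_stats, file.path(dir, "index_stats.csv"),
                   row.names = FALSE)
  fits <- lapply(study$ratio_analysis, function(ra) list(
    spearman_rho = ra$spearman$rho, spearman_p = ra$spearman$p,
    fit = if (!is.null(ra$fit)) ra$fit[c("a", "b", "c", "nrmse", "n")] else NULL))
  jsonlite::write_json(fits, file.path(dir, "ratio_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Scatter of V_dose ratios against reference volume with the fitted curve
#'
#' @param study a `study_result`.
#' @param perturbation which perturbation to plot (default: first).
#' @param path optional output file (png/svg by extension).
#' @return the ggplot object (requires ggplot2).
#' @export
plot_ratio_fit <- function(study, perturbation = names(study$ratio_analysis)[1],
                           path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  rec <- study$records
  rec <- rec[rec$perturbation == perturbation & rec$quantity != "V30Gy" &
               grepl("^V[0-9]", rec$quantity) & is.finite(rec$ratio), ]
  fit <- study$ratio_analysis[[perturbation]]$fit
  xs <- exp(seq(log(min(rec$v_ref)), log(max(rec$v_ref)), length.out = 200))
  p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$v_ref, y = .data$ratio)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "V_dose(ref) [cm^3]",
                  y = "V_dose(eval) / V_dose(ref)",
                  title = perturbation)
  if (!is.null(fit))
    p <- p + ggplot2::geom_line(
      data = data.frame(v_ref = xs, ratio = fit$fitted(xs)),
      colour = "red")
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 6, height = 4)
  p
}
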