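#' Gated image stack for one field of view
#'
#' The raw input of the pipeline: one FOV's temporal sequence of time-gated
#' intensity frames, in camera digital numbers (DN), with the acquisition
#' template that describes gate delays and frame roles.
#'
#' Pixel coordinates are row-major and 0-based everywhere in this package's
#' tables and outputs; frames are stored as R matrices indexed
#' `[row + 1, col + 1]`.
#'
#' @param frames List of numeric matrices (one per temporal frame), all of
#'   the template's frame shape, values >= 0.
#' @param template An [acq_template()].
#' @param fov_id,well_id,strain_id Identifiers (character scalars).
#' @param fixed_background_dn Scalar camera offset + ambient level (DN),
#'   subtracted during intensity integration.
#' @param source Optional provenance string (file path).
#' @return An object of class `gated_stack`.
#' @export
gated_stack <- function(frames, template, fov_id = "fov", well_id = "well",
                        strain_id = "strain", fixed_background_dn = 0,
                        source = NA_character_) {
  stopifnot(is_acq_template(template), is.list(frames))
  if (length(frames) != template$n_frames) {
    stop("stack has ", length(frames), " frames but the template requires ",
         template$n_frames)
  }
  for (i in seq_along(frames)) {
    d <- dim(frames[[i]])
    if (is.null(d) || !all(d == template$frame_shape)) {
      stop("frame ", i, " has shape ", paste(d, collapse = "x"),
           " but the template requires ",
           paste(template$frame_shape, collapse = "x"))
    }
    if (any(frames[[i]] < 0)) {
      stop("frame ", i, " contains negative intensities")
    }
  }
  structure(
    list(frames = frames, template = template, fov_id = fov_id,
         well_id = well_id, strain_id = strain_id,
         fixed_background_dn = fixed_background_dn, source = source),
    class = "gated_stack"
  )
}

is_gated_stack <- function(x) inherits(x, "gated_stack")

#' @export
print.gated_stack <- function(x, ...) {
  cat("<gated_stack>", x$fov_id, "(well", x$well_id, ", strain",
      x$strain_id, "):", length(x$frames), "frames of",
      paste(x$template$frame_shape, collapse = "x"), "px\n")
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".delays.txt")

#' Write a gated stack as multi-page TIFF plus sidecar delay table
#'
#' Frames are written as 16-bit unsigned integer DN (the camera's native
#' range), one TIFF page per temporal frame in acquisition order. The gate
#' delay and role of every frame go to a plain-text sidecar
#' `<path>.delays.txt` with columns `delay_ns role`, one line per frame —
#' the delay-metadata dialect this package reads back. Integer DN in
#' `[0, 65535]` round-trip bit-exactly.
#'
#' @param stack A [gated_stack()].
#' @param path Output TIFF path.
#' @param quantize If `TRUE`, round non-integer frame values to integer DN;
#'   if `FALSE` (default), non-integer frames are an error, so accidental
#'   loss of precision is impossible.
#' @return `path`, invisibly.
#' @export
write_fov_stack <- function(stack, path, quantize = FALSE) {
  stopifnot(is_gated_stack(stack))
  pages <- lapply(seq_along(stack$frames), function(i) {
    f <- stack$frames[[i]]
    if (quantize) f <- round(f)
    if (max(abs(f - round(f))) > 1e-6) {
      stop("frame ", i, " has non-integer DN values; pass quantize = TRUE ",
           "to round them at write time")
    }
    if (max(f) > 65535) {
      stop("frame ", i, " exceeds the 16-bit DN range (max ", max(f), ")")
    }
    round(f) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  tpl <- stack$template
  hdr <- c(
    paste0("# period_ns: ", format(tpl$period_ns, digits = 15)),
    paste0("# gate_width_ns: ", format(tpl$gate_width_ns, digits = 15)),
    paste0("# pixel_size_nm: ", format(tpl$pixel_size_nm, digits = 15)),
    paste0("# fixed_background_dn: ",
           format(stack$fixed_background_dn, digits = 15)),
    paste0("# fov_id: ", stack$fov_id),
    paste0("# well_id: ", stack$well_id),
    paste0("# strain_id: ", stack$strain_id)
  )
  body <- paste(format(tpl$frame_delays_ns, digits = 15, trim = TRUE),
                tpl$frame_roles)
  writeLines(c(hdr, body), sidecar_path(path))
  invisible(path)
}

#' Read a gated stack from a multi-page TIFF
#'
#' Delay and role metadata are resolved in priority order: an explicit
#' `template` argument; otherwise the sidecar delay table `<path>.delays.txt`
#' written by [write_fov_stack()] (delay per line; an optional second column
#' gives the frame role, defaulting to `flim`). With neither source of delay
#' information, reading fails with an instruction to supply a sidecar.
#'
#' @param path Multi-page TIFF path.
#' @param template Optional [acq_template()] overriding sidecar metadata.
#' @param fov_id,well_id,strain_id Identifier overrides; default to sidecar
#'   values or the file name.
#' @param fixed_background_dn Override for the fixed background (DN).
#' @return A [gated_stack()] with frames in acquisition order and provenance
#'   recorded in `$source`.
#' @export
read_fov_stack <- function(path, template = NULL, fov_id = NULL,
                           well_id = NULL, strain_id = NULL,
                           fixed_background_dn = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) round(p * 65535))
  meta <- list()
  sc <- sidecar_path(path)
  if (is.null(template)) {
    if (!file.exists(sc)) {
      stop("no delay metadata for ", path, ": supply a template or provide ",
           "a sidecar delay table at ", sc,
           " (one 'delay_ns [role]' line per frame)")
    }
    lines <- readLines(sc)
    hdr <- grep("^#", lines, value = TRUE)
    get_meta <- function(key, cast = identity) {
      m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
      if (!length(m)) return(NULL)
      cast(sub(paste0("^#\\s*", key, ":\\s*"), "", m[1]))
    }
    meta <- list(
      period_ns = get_meta("period_ns", as.numeric),
      gate_width_ns = get_meta("gate_width_ns", as.numeric),
      pixel_size_nm = get_meta("pixel_size_nm", as.numeric),
      fixed_background_dn = get_meta("fixed_background_dn", as.numeric),
      fov_id = get_meta("fov_id"),
      well_id = get_meta("well_id"),
      strain_id = get_meta("strain_id")
    )
    body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    parts <- strsplit(trimws(body), "\\s+")
    delays <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
    roles <- vapply(parts, function(p) {
      if (length(p) >= 2) p[2] else "flim"
    }, character(1))
    if (length(delays) != length(frames)) {
      stop("sidecar ", sc, " lists ", length(delays), " frames but ", path,
           " has ", length(frames), " pages")
    }
    template <- acq_template(
      period_ns = meta$period_ns %||% 12.5,
      gate_width_ns = meta$gate_width_ns %||% 4,
      delays_ns = delays[roles == "flim"],
      n_prebleach = sum(roles == "prebleach"),
      frame_shape = dim(frames[[1]]),
      pixel_size_nm = meta$pixel_size_nm %||% 615
    )
  }
  gated_stack(
    frames, template,
    fov_id = fov_id %||% meta$fov_id %||%
      tools::file_path_sans_ext(basename(path)),
    well_id = well_id %||% meta$well_id %||% "well",
    strain_id = strain_id %||% meta$strain_id %||% "strain",
    fixed_background_dn = fixed_background_dn %||%
      meta$fixed_background_dn %||% 0,
    source = path
  )
}

# ---------------------------------------------------------------------------
# Plate layout
# ---------------------------------------------------------------------------

#' Plate layout: wells, strains, groups, roles
#'
#' Maps each well to a strain, a comparison group, and a role. Roles are
#' `query`, `negative_control` (the donor-only strain the queries are
#' compared against) or `positive_control`. Every group must contain exactly
#' one negative-control strain.
#'
#' @param wells A data frame with columns `well_id`, `strain_id`, `group_id`,
#'   `role`.
#' @param fovs_per_well Fields of view imaged per well (default 15).
#' @param replicate_wells_per_strain Wells per strain (default 3), so each
#'   strain contributes `3 * 15 = 45` FOVs per plate run.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(wells, fovs_per_well = 15L,
                         replicate_wells_per_strain = 3L) {
  stopifnot(is.data.frame(wells),
            all(c("well_id", "strain_id", "group_id", "role") %in%
                  names(wells)))
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  if (anyDuplicated(wells$well_id)) {
    stop("duplicate well ids: ",
         paste(unique(wells$well_id[duplicated(wells$well_id)]),
               collapse = ", "))
  }
  bad <- setdiff(unique(wells$role),
                 c("query", "negative_control", "positive_control"))
  if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
  for (g in unique(wells$group_id)) {
    ctrl <- unique(wells$strain_id[wells$group_id == g &
                                     wells$role == "negative_control"])
    if (length(ctrl) != 1L) {
      stop("group '", g, "' must contain exactly one negative_control ",
           "strain (found ", length(ctrl), ")")
    }
  }
  structure(
    list(wells = wells, fovs_per_well = as.integer(fovs_per_well),
         replicate_wells_per_strain = as.integer(replicate_wells_per_strain)),
    class = "plate_layout"
  )
}

is_plate_layout <- function(x) inherits(x, "plate_layout")

#' @export
print.plate_layout <- function(x, ...) {
  cat("<plate_layout>", nrow(x$wells), "wells,",
      length(unique(x$wells$strain_id)), "strains,",
      length(unique(x$wells$group_id)), "groups,",
      x$fovs_per_well, "FOVs/well\n")
  invisible(x)
}

#' Load a plate layout from a YAML config
#'
#' The config has a `wells` mapping (`well_id: {strain, group, role}`) plus
#' optional `fovs_per_well` and `replicate_wells_per_strain` scalars.
#'
#' @param path YAML file path.
#' @return A [plate_layout()].
#' @export
load_plate_layout <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$wells) || !length(cfg$wells)) {
    stop("plate layout ", path, " has no 'wells' section")
  }
  wl <- cfg$wells
  wells <- data.frame(
    well_id = names(wl),
    strain_id = vapply(wl, function(w) as.character(w$strain), character(1)),
    group_id = vapply(wl, function(w) as.character(w$group %||% "g1"),
                      character(1)),
    role = vapply(wl, function(w) as.character(w$role %||% "query"),
                  character(1)),
    stringsAsFactors = FALSE
  )
  rownames(wells) <- NULL
  plate_layout(wells,
               fovs_per_well = cfg$fovs_per_well %||% 15L,
               replicate_wells_per_strain =
                 cfg$replicate_wells_per_strain %||% 3L)
}

#' @rdname load_plate_layout
#' @param layout A `plate_layout` (for writing).
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(is_plate_layout(layout))
  wl <- lapply(seq_len(nrow(layout$wells)), function(i) {
    list(strain = layout$wells$strain_id[i],
         group = layout$wells$group_id[i],
         role = layout$wells$role[i])
  })
  names(wl) <- layout$wells$well_id
  yaml::write_yaml(list(
    fovs_per_well = layout$fovs_per_well,
    replicate_wells_per_strain = layout$replicate_wells_per_strain,
    wells = wl
  ), path)
  invisible(path)
}

#' Enumerate the FOV records of a plate layout
#'
#' @param layout A [plate_layout()].
#' @return Data frame with one row per (well, FOV): `well_id`, `strain_id`,
#'   `group_id`, `role`, `fov_index` (1-based within well), `fov_id`.
#' @export
enumerate_fovs <- function(layout) {
  stopifnot(is_plate_layout(layout))
  w <- layout$wells
  n <- layout$fovs_per_well
  out <- w[rep(seq_len(nrow(w)), each = n), , drop = FALSE]
  out$fov_index <- rep(seq_len(n), times = nrow(w))
  out$fov_id <- sprintf("%s_fov%02d", out$well_id, out$fov_index)
  rownames(out) <- NULL
  out
}

#' Build a simple layout programmatically
#'
#' Assigns `replicate_wells_per_strain` wells to each strain, row by row on
#' a 96-well grid.
#'
#' @param strains Data frame with columns `strain_id`, `group_id`, `role`.
#' @inheritParams plate_layout
#' @return A [plate_layout()].
#' @export
make_plate_layout <- function(strains, fovs_per_well = 15L,
                              replicate_wells_per_strain = 3L) {
  stopifnot(is.data.frame(strains),
            all(c("strain_id", "group_id", "role") %in% names(strains)))
  nw <- nrow(strains) * replicate_wells_per_strain
  rows <- LETTERS[1:8]
  ids <- as.vector(t(outer(rows, 1:12, function(r, c) paste0(r, c))))
  if (nw > length(ids)) stop("layout needs ", nw, " wells; a 96-well plate has 96")
  wells <- data.frame(
    well_id = ids[seq_len(nw)],
    strain_id = rep(strains$strain_id, each = replicate_wells_per_strain),
    group_id = rep(strains$group_id, each = replicate_wells_per_strain),
    role = rep(strains$role, each = replicate_wells_per_strain),
    stringsAsFactors = FALSE
  )
  plate_layout(wells, fovs_per_well, replicate_wells_per_strain)
}
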