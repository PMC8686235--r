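#' Electrode montages and the Cz-origin coordinate frame
#'
#' A montage is a tibble with one row per electrode (`label`, `x`, `y`, `z`),
#' coordinates in centimeters in the Cz-origin frame: the vertex electrode Cz
#' sits at (0, 0, 0), +x points toward the right preauricular point, +y toward
#' the nasion, +z dorsally (right-handed). Fiducial landmarks (NAS, INI, LPA,
#' RPA) are carried in the `fiducials` attribute and are only consumed by
#' [to_cz_frame()].
#'
#' @name montage
NULL

# spherical linear interpolation between two unit vectors
.slerp <- function(u0, u1, t) {
  om <- acos(max(-1, min(1, sum(u0 * u1))))
  (sin((1 - t) * om) * u0 + sin(t * om) * u1) / sin(om)
}

#' Idealized 63-channel extended 10-20 montage
#'
#' Builds the default 63-electrode montage on a spherical head. Electrodes are
#' placed by the standard 10-20 construction: 10%/20% fractions along the
#' nasion-inion midline arc, the ear-to-ear coronal arc, the 10% circumferential
#' ring, and great-circle interpolation for the intermediate rows, plus the
#' low mastoid pair TP9/TP10. Coordinates are returned in the Cz-origin frame
#' in centimeters.
#'
#' @param radius Scalp sphere radius in cm.
#' @return A montage tibble (63 rows: `label`, `x`, `y`, `z`) with a
#'   `fiducials` attribute.
#' @examples
#' m <- default_montage()
#' m[m$label == "Cz", ]
#' @export
default_montage <- function(radius = 9) {
  deg <- pi / 180
  rows <- list()
  add <- function(label, u) rows[[length(rows) + 1L]] <<- list(label = label, u = u)

  # midline arc, angle from vertex, anterior positive
  mid <- c(Fpz = 72, AFz = 54, Fz = 36, FCz = 18, Cz = 0,
           CPz = -18, Pz = -36, POz = -54, Oz = -72)
  mid_u <- lapply(mid, function(a) c(0, sin(a * deg), cos(a * deg)))
  # coronal arc through the ears, right positive
  cor_row <- c(T7 = -72, C5 = -54, C3 = -36, C1 = -18,
               C2 = 18, C4 = 36, C6 = 54, T8 = 72)
  cor_u <- lapply(cor_row, function(b) c(sin(b * deg), 0, cos(b * deg)))
  # 10% circumferential ring (inclination 72 deg), azimuth from anterior midline,
  # right positive
  ring <- c(Fp1 = -18, Fp2 = 18, AF7 = -36, AF8 = 36, F7 = -54, F8 = 54,
            FT7 = -72, FT8 = 72, TP7 = -108, TP8 = 108, P7 = -126, P8 = 126,
            PO7 = -144, PO8 = 144, O1 = -162, O2 = 162)
  ring_u <- lapply(ring, function(p)
    c(sin(72 * deg) * sin(p * deg), sin(72 * deg) * cos(p * deg), cos(72 * deg)))

  # intermediate rows by slerp from the ring electrode to the midline electrode
  row_between <- function(lat_u, mid_u, labels) {
    ts <- seq_along(labels) / (length(labels) + 1L)
    Map(function(lab, t) add(lab, .slerp(lat_u, mid_u, t)), labels, ts)
  }

  add("Fp1", ring_u$Fp1); add("Fpz", mid_u$Fpz); add("Fp2", ring_u$Fp2)
  add("AF7", ring_u$AF7)
  add("AF3", .slerp(ring_u$AF7, mid_u$AFz, 0.5)); add("AFz", mid_u$AFz)
  add("AF4", .slerp(ring_u$AF8, mid_u$AFz, 0.5)); add("AF8", ring_u$AF8)
  add("F7", ring_u$F7)
  row_between(ring_u$F7, mid_u$Fz, c("F5", "F3", "F1"))
  add("Fz", mid_u$Fz)
  row_between(ring_u$F8, mid_u$Fz, c("F6", "F4", "F2"))
  add("F8", ring_u$F8)
  add("FT7", ring_u$FT7)
  row_between(ring_u$FT7, mid_u$FCz, c("FC5", "FC3", "FC1"))
  add("FCz", mid_u$FCz)
  row_between(ring_u$FT8, mid_u$FCz, c("FC6", "FC4", "FC2"))
  add("FT8", ring_u$FT8)
  for (lab in names(cor_u)[1:4]) add(lab, cor_u[[lab]])
  add("Cz", mid_u$Cz)
  for (lab in names(cor_u)[5:8]) add(lab, cor_u[[lab]])
  add("TP9", c(sin(-108 * deg), cos(-108 * deg), 0))
  add("TP7", ring_u$TP7)
  row_between(ring_u$TP7, mid_u$CPz, c("CP5", "CP3", "CP1"))
  add("CPz", mid_u$CPz)
  row_between(ring_u$TP8, mid_u$CPz, c("CP6", "CP4", "CP2"))
  add("TP8", ring_u$TP8)
  add("TP10", c(sin(108 * deg), cos(108 * deg), 0))
  add("P7", ring_u$P7)
  row_between(ring_u$P7, mid_u$Pz, c("P5", "P3", "P1"))
  add("Pz", mid_u$Pz)
  row_between(ring_u$P8, mid_u$Pz, c("P6", "P4", "P2"))
  add("P8", ring_u$P8)
  add("PO7", ring_u$PO7)
  add("PO3", .slerp(ring_u$PO7, mid_u$POz, 0.5)); add("POz", mid_u$POz)
  add("PO4", .slerp(ring_u$PO8, mid_u$POz, 0.5)); add("PO8", ring_u$PO8)
  add("O1", ring_u$O1); add("Oz", mid_u$Oz); add("O2", ring_u$O2)

  pos <- t(vapply(rows, function(r) radius * r$u - c(0, 0, radius), numeric(3)))
  out <- tibble::tibble(
    label = vapply(rows, `[[`, character(1), "label"),
    x = pos[, 1], y = pos[, 2], z = pos[, 3]
  )
  fid <- tibble::tibble(
    label = c("NAS", "INI", "LPA", "RPA"),
    x = c(0, 0, -radius, radius),
    y = c(radius, -radius, 0, 0),
    z = -radius
  )
  new_montage(out, fiducials = fid, radius = radius)
}

new_montage <- function(tbl, fiducials = NULL, radius = NA_real_) {
  tbl <- tibble::as_tibble(tbl)
  validate_montage(tbl)
  structure(tbl, fiducials = fiducials, radius = radius,
            class = c("eeg_montage", class(tbl)))
}

validate_montage <- function(tbl) {
  stopifnot(all(c("label", "x", "y", "z") %in% names(tbl)))
  dup <- tbl$label[duplicated(tbl$label)]
  if (length(dup) > 0) {
    abort(paste0("duplicated electrode label(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (!all(is.finite(as.matrix(tbl[c("x", "y", "z")])))) {
    abort("non-finite electrode position")
  }
  invisible(tbl)
}

#' Read an electrode position file
#'
#' Parses a tab-separated file with rows `label<TAB>x<TAB>y<TAB>z` (cm).
#' Lines starting with `#` are comments. The reserved labels NAS, INI, LPA,
#' RPA are treated as fiducial landmarks and stored in the `fiducials`
#' attribute rather than as electrodes. Cz must be present.
#'
#' @param path Path to the TSV file.
#' @return A montage tibble.
#' @export
load_montage <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) abort("empty electrode position file")
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 4L)
  if (length(bad) > 0) {
    abort(sprintf("malformed electrode row at line %d: '%s'",
                  keep[bad[1]], lines[keep[bad[1]]]))
  }
  tbl <- tibble::tibble(
    label = vapply(parts, `[[`, character(1), 1L),
    x = as.numeric(vapply(parts, `[[`, character(1), 2L)),
    y = as.numeric(vapply(parts, `[[`, character(1), 3L)),
    z = as.numeric(vapply(parts, `[[`, character(1), 4L))
  )
  if (anyNA(tbl[c("x", "y", "z")])) {
    i <- which(!stats::complete.cases(tbl))[1]
    abort(sprintf("non-numeric coordinate at line %d (label %s)", keep[i], tbl$label[i]))
  }
  fid_labels <- c("NAS", "INI", "LPA", "RPA")
  fid <- tbl[tbl$label %in% fid_labels, ]
  tbl <- tbl[!tbl$label %in% fid_labels, ]
  if (!"Cz" %in% tbl$label) abort("montage has no Cz electrode")
  new_montage(tbl, fiducials = if (nrow(fid)) fid else NULL)
}

#' Write a montage to an electrode position TSV
#'
#' @param montage A montage tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  fid <- attr(montage, "fiducials")
  tbl <- rbind(as.data.frame(montage)[c("label", "x", "y", "z")],
               if (!is.null(fid)) as.data.frame(fid)[c("label", "x", "y", "z")])
  lines <- c("# label\tx\ty\tz (cm, Cz-origin frame)",
             sprintf("%s\t%.10g\t%.10g\t%.10g", tbl$label, tbl$x, tbl$y, tbl$z))
  writeLines(lines, path)
  invisible(path)
}

#' Electrode positions as a matrix
#'
#' @param montage A montage tibble.
#' @param labels Optional electrode labels to select (in that order).
#' @return Numeric matrix (n x 3) with rownames set to labels.
#' @export
electrode_positions <- function(montage, labels = NULL) {
  pos <- as.matrix(as.data.frame(montage)[c("x", "y", "z")])
  rownames(pos) <- montage$label
  if (!is.null(labels)) {
    missing <- setdiff(labels, montage$label)
    if (length(missing) > 0) {
      abort(paste0("label(s) not in montage: ", paste(missing, collapse = ", ")))
    }
    pos <- pos[labels, , drop = FALSE]
  }
  pos
}

#' Transform digitizer-frame points into the Cz-origin frame
#'
#' Applies the rigid transform (rotation + translation, no scaling) that maps
#' the digitized Cz electrode to the origin, with +x toward the right
#' preauricular point, +y toward the nasion, and +z dorsal (right-handed).
#' Pairwise distances are preserved.
#'
#' @param points Numeric n x 3 matrix (or length-3 vector) of points in the
#'   raw digitizer frame.
#' @param montage Montage whose electrodes and fiducials are digitized in the
#'   same raw frame as `points`; must contain Cz and the NAS/LPA/RPA fiducials.
#' @return Transformed n x 3 matrix in the Cz-origin frame.
#' @export
to_cz_frame <- function(points, montage) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  fid <- attr(montage, "fiducials")
  if (is.null(fid) || !all(c("NAS", "LPA", "RPA") %in% fid$label)) {
    abort("montage lacks NAS/LPA/RPA fiducials required to define the frame")
  }
  fpos <- as.matrix(as.data.frame(fid)[c("x", "y", "z")])
  rownames(fpos) <- fid$label
  cz <- as.numeric(electrode_positions(montage, "Cz"))
  ex <- fpos["RPA", ] - fpos["LPA", ]
  nex <- sqrt(sum(ex^2))
  if (nex < 1e-12) abort("degenerate fiducials: LPA and RPA coincide")
  ex <- ex / nex
  mid <- (fpos["RPA", ] + fpos["LPA", ]) / 2
  ey <- fpos["NAS", ] - mid
  ey <- ey - sum(ey * ex) * ex
  ney <- sqrt(sum(ey^2))
  if (ney < 1e-12) abort("degenerate fiducials: nasion collinear with the ear axis")
  ey <- ey / ney
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- cbind(ex, ey, ez)
  sweep(points, 2, cz) %*% R
}

#' Default nested channel sets
#'
#' Five nested channel sets used for the montage-ablation analysis, from the
#' full 63-channel montage (Ch_Set1) down to 9 channels over the midline motor
#' strip (Ch_Set5). Only the 63/17/9 counts are anatomically fixed; the
#' intermediate memberships are configuration defaults and can be overridden
#' via [read_channel_sets()]. Ch_Set4 additionally carries per-hand variants
#' weighted toward the contralateral motor cortex.
#'
#' @return Named list; each element has `labels` and optionally `per_hand`.
#' @export
default_channel_sets <- function() {
  m <- default_montage()
  ring <- c("Fp1", "Fpz", "Fp2", "AF7", "AF8", "F7", "F8", "FT7", "FT8",
            "T7", "T8", "TP7", "TP8", "TP9", "TP10", "P7", "P8",
            "PO7", "PO8", "O1", "Oz", "O2")
  set5 <- c("FC1", "FC2", "C1", "Cz", "C2", "C3", "C4", "CP1", "CP2")
  set4 <- c("FC3", "FC1", "FCz", "FC2", "FC4",
            "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
            "CP3", "CP1", "CPz", "CP2", "CP4")
  set4_right <- c("FC5", "FC3", "FC1", "FCz", "FC2",
                  "C5", "C3", "C1", "Cz", "C2", "C4",
                  "CP5", "CP3", "CP1", "CPz", "CP2", "CP4")
  set4_left <- c("FC6", "FC4", "FC2", "FCz", "FC1",
                 "C6", "C4", "C2", "Cz", "C1", "C3",
                 "CP6", "CP4", "CP2", "CPz", "CP1", "CP3")
  set3 <- unique(c(set4, "FC5", "FC6", "CP5", "CP6",
                   "F5", "F3", "F1", "Fz", "F2", "F4", "F6",
                   "P5", "P3", "P1", "Pz", "P2", "P4", "P6"))
  set2 <- setdiff(m$label, ring)
  list(
    Ch_Set1 = list(labels = m$label),
    Ch_Set2 = list(labels = set2),
    Ch_Set3 = list(labels = set3),
    Ch_Set4 = list(labels = set4,
                   per_hand = list(left = set4_left, right = set4_right)),
    Ch_Set5 = list(labels = set5)
  )
}

#' Read channel-set definitions from a YAML file
#'
#' Each top-level key names a set; its value is either a list of labels or a
#' mapping with `labels` and an optional `per_hand` mapping (hand -> labels).
#'
#' @param path YAML file path.
#' @return Named list in the shape of [default_channel_sets()].
#' @export
read_channel_sets <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s) {
    if (is.character(s) || is.null(names(s))) list(labels = unlist(s)) else s
  })
}

#' Select a channel set
#'
#' @param montage Montage the labels must belong to.
#' @param set_name Name of a configured set (default config: Ch_Set1..Ch_Set5).
#' @param hand `"left"`, `"right"`, or `"none"`. Required for sets with
#'   per-hand (contralateral) variants, e.g. Ch_Set4.
#' @param sets Channel-set configuration, defaults to [default_channel_sets()].
#' @return Character vector of electrode labels, with attributes `set_name`
#'   and `hand`.
#' @export
channel_set <- function(montage, set_name, hand = c("none", "left", "right"),
                        sets = default_channel_sets()) {
  hand <- match.arg(hand)
  if (!set_name %in% names(sets)) {
    abort(sprintf("unknown channel set '%s'; known sets: %s",
                  set_name, paste(names(sets), collapse = ", ")))
  }
  s <- sets[[set_name]]
  if (!is.null(s$per_hand)) {
    if (hand == "none") {
      abort(sprintf("channel set '%s' has per-hand variants; specify hand = 'left' or 'right'",
                    set_name))
    }
    labels <- s$per_hand[[hand]]
  } else {
    labels <- s$labels
  }
  missing <- setdiff(labels, montage$label)
  if (length(missing) > 0) {
    abort(paste0("channel set labels not in montage: ", paste(missing, collapse = ", ")))
  }
  structure(labels, set_name = set_name, hand = hand)
}
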