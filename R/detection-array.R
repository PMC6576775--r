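#' Detection array: site x camera x occasion observations
#'
#' A `detection_array` holds the raw survey record of a camera-trap study:
#' for each site, each camera, and each daily survey occasion, whether the
#' target species was photographed (1), not photographed while the camera was
#' active (0), or whether the camera-day yielded no data at all (`NA`, a
#' "missing visit": camera failure, snow burial, battery death). Sites may be
#' surveyed for different numbers of days.
#'
#' @param obs numeric array of dimension `n_sites x n_cameras x max(occasions)`
#'   with values in `{0, 1, NA}`. Cells beyond a site's own occasion count
#'   must be `NA`.
#' @param site_ids character vector of site identifiers (unique, ordered).
#' @param camera_labels character vector of camera labels (unique, ordered);
#'   defaults `A`-`E` match a five-camera T-shaped array.
#' @param occasions integer vector, one entry per site, of daily survey
#'   occasions (>= 1).
#' @return an object of class `detection_array`.
#' @examples
#' obs <- array(0, dim = c(2, 5, 3))
#' obs[1, 1, 2] <- 1
#' d <- detection_array(obs, site_ids = c("s1", "s2"))
#' naive_summaries(d)
#' @export
detection_array <- function(obs, site_ids = NULL, camera_labels = NULL,
                            occasions = NULL) {
  if (!is.array(obs) || length(dim(obs)) != 3L)
    stop("'obs' must be a 3-dimensional array (site x camera x occasion)")
  d <- dim(obs)
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(d[1]))
  if (is.null(camera_labels)) camera_labels <- LETTERS[seq_len(d[2])]
  if (is.null(occasions)) occasions <- rep(d[3], d[1])
  site_ids <- as.character(site_ids)
  camera_labels <- as.character(camera_labels)
  occasions <- as.integer(occasions)
  if (length(site_ids) != d[1]) stop("length(site_ids) must match dim(obs)[1]")
  if (length(camera_labels) != d[2])
    stop("length(camera_labels) must match dim(obs)[2]")
  if (length(occasions) != d[1]) stop("one occasion count per site required")
  if (anyDuplicated(site_ids)) stop("duplicate site_ids")
  if (anyDuplicated(camera_labels)) stop("duplicate camera_labels")
  if (any(occasions < 1L)) stop("every site needs >= 1 occasion")
  if (max(occasions) > d[3]) stop("occasions exceed dim(obs)[3]")
  bad <- !(obs %in% c(0, 1) | is.na(obs))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "invalid observation value %s at site '%s', camera '%s', occasion %d (must be 0, 1 or NA)",
      format(obs[idx[1], idx[2], idx[3]]), site_ids[idx[1]],
      camera_labels[idx[2]], idx[3]))
  }
  # beyond a site's survey window the array is structurally empty
  for (i in seq_len(d[1])) {
    if (occasions[i] < d[3]) obs[i, , (occasions[i] + 1L):d[3]] <- NA
  }
  dimnames(obs) <- list(site_ids, camera_labels, NULL)
  structure(list(obs = obs, site_ids = site_ids,
                 camera_labels = camera_labels, occasions = occasions),
            class = "detection_array")
}

#' @export
print.detection_array <- function(x, ...) {
  cat("Detection array:", length(x$site_ids), "sites x",
      length(x$camera_labels), "cameras,",
      "occasions", min(x$occasions), "-", max(x$occasions), "days\n")
  s <- naive_summaries(x)
  cat("  detections at", s$cameras_with_detection, "cameras over",
      s$nights_with_detection, "trap-nights;",
      s$active_trap_nights, "active trap-nights total\n")
  invisible(x)
}

#' Read per-camera detection histories from delimited text
#'
#' Long layout: columns `site`, `camera`, `occasion`, `value` with `value`
#' in `{0, 1, NA}`; one row per recorded camera-day (rows may appear in any
#' order). Wide layout: columns `site`, `camera`, `occ_1` ... `occ_T`.
#'
#' @param path path to a comma-delimited text file.
#' @param layout `"long"` (default) or `"wide"`.
#' @return a [detection_array()].
#' @export
read_detections <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (layout == "long") {
    need <- c("site", "camera", "occasion", "value")
    if (!all(need %in% names(df)))
      stop("long layout requires columns: ", paste(need, collapse = ", "))
    df$site <- as.character(df$site)
    df$camera <- as.character(df$camera)
    df$occasion <- as.integer(df$occasion)
    key <- paste(df$site, df$camera, df$occasion, sep = "\r")
    if (anyDuplicated(key)) {
      k <- key[duplicated(key)][1]
      stop("duplicate record for (site, camera, occasion): ",
           gsub("\r", ", ", k))
    }
    ok <- is.na(df$value) | df$value %in% c(0, 1)
    if (any(!ok)) {
      r <- df[which(!ok)[1], ]
      stop(sprintf(
        "invalid value '%s' at site '%s', camera '%s', occasion %d",
        r$value, r$site, r$camera, r$occasion))
    }
    sites <- sort(unique(df$site))
    cams <- sort(unique(df$camera))
    occasions <- unname(vapply(sites, function(s)
      max(df$occasion[df$site == s]), integer(1)))
    obs <- array(NA_real_, dim = c(length(sites), length(cams),
                                   max(occasions)))
    i <- match(df$site, sites)
    j <- match(df$camera, cams)
    obs[cbind(i, j, df$occasion)] <- df$value
    detection_array(obs, sites, cams, occasions)
  } else {
    occ_cols <- grep("^occ_[0-9]+$", names(df), value = TRUE)
    if (!all(c("site", "camera") %in% names(df)) || length(occ_cols) == 0)
      stop("wide layout requires columns site, camera, occ_1..occ_T")
    occ_cols <- occ_cols[order(as.integer(sub("occ_", "", occ_cols)))]
    df$site <- as.character(df$site)
    df$camera <- as.character(df$camera)
    if (anyDuplicated(paste(df$site, df$camera, sep = "\r")))
      stop("duplicate (site, camera) row in wide layout")
    sites <- sort(unique(df$site))
    cams <- sort(unique(df$camera))
    Tmax <- length(occ_cols)
    obs <- array(NA_real_, dim = c(length(sites), length(cams), Tmax))
    for (r in seq_len(nrow(df))) {
      v <- as.numeric(df[r, occ_cols])
      bad <- which(!(is.na(v) | v %in% c(0, 1)))
      if (length(bad))
        stop(sprintf("invalid value '%s' at site '%s', camera '%s', occasion %d",
                     format(v[bad[1]]), df$site[r], df$camera[r], bad[1]))
      obs[match(df$site[r], sites), match(df$camera[r], cams), ] <- v
    }
    occasions <- vapply(seq_along(sites), function(i) {
      nz <- which(apply(!is.na(obs[i, , , drop = FALSE]), 3, any))
      if (length(nz)) max(nz) else Tmax
    }, integer(1))
    detection_array(obs, sites, cams, occasions)
  }
}

#' Write a detection array to delimited text
#'
#' The long layout writes one row per camera-day inside each site's survey
#' window, with `NA` for missing visits, so that [read_detections()]
#' reproduces the array exactly.
#'
#' @param d a [detection_array()].
#' @param path output file path.
#' @param layout `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_detections <- function(d, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  stopifnot(inherits(d, "detection_array"))
  if (layout == "long") {
    rows <- do.call(rbind, lapply(seq_along(d$site_ids), function(i) {
      expand.grid(site = d$site_ids[i], camera = d$camera_labels,
                  occasion = seq_len(d$occasions[i]),
                  stringsAsFactors = FALSE)
    }))
    rows$value <- d$obs[cbind(match(rows$site, d$site_ids),
                              match(rows$camera, d$camera_labels),
                              rows$occasion)]
    utils::write.csv(rows, path, row.names = FALSE, na = "NA")
  } else {
    Tmax <- dim(d$obs)[3]
    rows <- expand.grid(camera = d$camera_labels, site = d$site_ids,
                        stringsAsFactors = FALSE)[, c("site", "camera")]
    m <- t(apply(rows, 1, function(r)
      d$obs[match(r[["site"]], d$site_ids),
            match(r[["camera"]], d$camera_labels), ]))
    colnames(m) <- paste0("occ_", seq_len(Tmax))
    utils::write.csv(cbind(rows, m), path, row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Naive detection summaries
#'
#' Raw counts before any modelling: how many cameras recorded the species at
#' least once, how many camera-trap-nights had a detection, and the total
#' number of active camera-trap-nights (missing visits excluded).
#'
#' @param d a [detection_array()].
#' @return a one-row data frame with columns `cameras_with_detection`,
#'   `nights_with_detection`, `active_trap_nights`.
#' @export
naive_summaries <- function(d) {
  stopifnot(inherits(d, "detection_array"))
  det_cam <- apply(d$obs == 1, c(1, 2), any, na.rm = TRUE)
  data.frame(
    cameras_with_detection = sum(det_cam),
    nights_with_detection = sum(d$obs == 1, na.rm = TRUE),
    active_trap_nights = sum(!is.na(d$obs)))
}
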