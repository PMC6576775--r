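#' Method map: pooling schemes over co-located cameras
#'
#' A survey "method" is a named subset of the cameras at a site whose daily
#' histories are combined by logical OR. The default map encodes the standard
#' five-camera T-array comparison: a single camera, pairs and triples at
#' short (100 m) or long (150 m) spacing.
#'
#' @param methods a named list; each element is a character vector of camera
#'   labels. Names are the method ids.
#' @param spacing character vector (same length), each `"short"`, `"long"`
#'   or `"n/a"`.
#' @return an object of class `method_map`: a data frame with columns
#'   `method_id`, `cameras` (list column), `spacing`, `n_cameras`.
#' @examples
#' default_method_map()
#' method_map(list(pair_AB = c("A", "B")), spacing = "short")
#' @export
method_map <- function(methods, spacing = NULL) {
  if (is.null(names(methods)) || any(names(methods) == ""))
    stop("'methods' must be a fully named list of camera-label vectors")
  if (anyDuplicated(names(methods))) stop("duplicate method ids")
  if (is.null(spacing)) spacing <- rep("n/a", length(methods))
  if (length(spacing) != length(methods))
    stop("one spacing tag per method required")
  if (!all(spacing %in% c("short", "long", "n/a")))
    stop("spacing must be 'short', 'long' or 'n/a'")
  for (m in names(methods)) {
    cams <- methods[[m]]
    if (length(cams) < 1L || anyDuplicated(cams))
      stop("method '", m, "' must list >= 1 distinct camera labels")
  }
  out <- data.frame(method_id = names(methods),
                    spacing = spacing,
                    n_cameras = vapply(methods, length, integer(1)),
                    stringsAsFactors = FALSE)
  out$cameras <- unname(lapply(methods, as.character))
  class(out) <- c("method_map", "data.frame")
  rownames(out) <- NULL
  out
}

#' @rdname method_map
#' @export
default_method_map <- function() {
  method_map(
    list(m1 = "A",
         m2 = c("B", "C"),
         m3 = c("A", "B", "C"),
         m4 = c("D", "E"),
         m5 = c("B", "D", "E")),
    spacing = c("n/a", "short", "short", "long", "long"))
}

#' @export
print.method_map <- function(x, ...) {
  cat("Method map (", nrow(x), " pooling methods):\n", sep = "")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s: {%s} [%s]\n", x$method_id[i],
                paste(x$cameras[[i]], collapse = ","), x$spacing[i]))
  invisible(x)
}

#' Read a method map from a YAML config file
#'
#' Expects a list of entries with fields `id`, `cameras`, and optionally
#' `spacing`.
#'
#' @param path path to a YAML file.
#' @return a [method_map()].
#' @export
read_method_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  methods <- stats::setNames(
    lapply(cfg, function(m) as.character(m$cameras)),
    vapply(cfg, function(m) as.character(m$id), character(1)))
  spacing <- vapply(cfg, function(m)
    if (is.null(m$spacing)) "n/a" else as.character(m$spacing), character(1))
  method_map(methods, spacing)
}

#' Pool per-camera histories into method-level histories
#'
#' For each site, occasion, and method, the pooled value is 1 if any member
#' camera detected the species that day, 0 if at least one member camera was
#' active and none detected, and missing only when every member camera was
#' missing that day — any active camera makes the occasion informative.
#'
#' @param d a [detection_array()].
#' @param map a [method_map()]; defaults to [default_method_map()].
#' @return an object of class `pooled_history` with fields `obs` (site x
#'   method x occasion array in `{0, 1, NA}`), `site_ids`, `method_ids`,
#'   `occasions`, and the `map` used.
#' @export
pool_histories <- function(d, map = default_method_map()) {
  stopifnot(inherits(d, "detection_array"), inherits(map, "method_map"))
  unknown <- setdiff(unlist(map$cameras), d$camera_labels)
  if (length(unknown))
    stop("method map references unknown camera(s): ",
         paste(unknown, collapse = ", "))
  n <- length(d$site_ids)
  Tmax <- dim(d$obs)[3]
  S <- nrow(map)
  obs <- array(NA_real_, dim = c(n, S, Tmax),
               dimnames = list(d$site_ids, map$method_id, NULL))
  for (s in seq_len(S)) {
    sub <- d$obs[, match(map$cameras[[s]], d$camera_labels), , drop = FALSE]
    any1 <- apply(sub == 1, c(1, 3), any, na.rm = TRUE)
    allNA <- apply(is.na(sub), c(1, 3), all)
    v <- ifelse(any1, 1, 0)
    v[allNA] <- NA
    obs[, s, ] <- v
  }
  structure(list(obs = obs, site_ids = d$site_ids,
                 method_ids = map$method_id, occasions = d$occasions,
                 map = map),
            class = "pooled_history")
}

#' @export
print.pooled_history <- function(x, ...) {
  cat("Pooled detection histories:", length(x$site_ids), "sites x",
      length(x$method_ids), "methods,",
      "occasions", min(x$occasions), "-", max(x$occasions), "days\n")
  det <- apply(x$obs == 1, 2, sum, na.rm = TRUE)
  cat("  detection-days per method:",
      paste(sprintf("%s=%d", x$method_ids, det), collapse = ", "), "\n")
  invisible(x)
}

#' Write pooled histories as long-format CSV
#'
#' Columns `site`, `method`, `occasion`, `value` (NA for missing).
#'
#' @param p a `pooled_history`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pooled <- function(p, path) {
  stopifnot(inherits(p, "pooled_history"))
  rows <- do.call(rbind, lapply(seq_along(p$site_ids), function(i) {
    expand.grid(site = p$site_ids[i], method = p$method_ids,
                occasion = seq_len(p$occasions[i]),
                stringsAsFactors = FALSE)
  }))
  rows$value <- p$obs[cbind(match(rows$site, p$site_ids),
                            match(rows$method, p$method_ids),
                            rows$occasion)]
  utils::write.csv(rows, path, row.names = FALSE, na = "NA")
  invisible(path)
}
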