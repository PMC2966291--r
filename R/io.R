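#' Read molecules from a SMILES line file
#'
#' One molecule per non-empty, non-comment line: the first
#' whitespace-delimited field is the molecular string, an optional second
#' field is its identifier (auto-numbered from 1 otherwise).
#'
#' @param path Path to a `.smi` file.
#' @return Data frame with columns `id` and `molecule`.
#' @export
ngn_read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no molecules in '", path, "'", call. = FALSE)
  parts <- strsplit(lines, "\\s+")
  mol <- vapply(parts, `[[`, "", 1L)
  id <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) >= 2L) parts[[i]][2L] else as.character(i), "")
  data.frame(id = id, molecule = mol, stringsAsFactors = FALSE)
}

#' Read a dataset table (molecule, target and/or label)
#'
#' The CSV must have a `molecule` column and at least one of `target`
#' (numeric), `label` (`pos`/`neg`/1/0, case-insensitive) or `activity`
#' (numeric, converted to labels via `theta`).  An `id` column is kept if
#' present.
#'
#' @param path Path to a CSV file.
#' @param theta Optional threshold: rows gain labels
#'   via [ngn_label_by_threshold()] applied to the `activity` column.
#' @param direction Threshold direction, see [ngn_label_by_threshold()].
#' @return Data frame with columns `id`, `molecule`, and whichever of
#'   `target`, `activity`, `label` are available.
#' @export
ngn_read_dataset <- function(path, theta = NULL, direction = "ge") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"molecule" %in% names(df))
    stop("schema error: '", path, "' lacks a 'molecule' column", call. = FALSE)
  if (!any(c("target", "label", "activity") %in% names(df)))
    stop("schema error: need a 'target', 'label' or 'activity' column",
         call. = FALSE)
  if (any(!nzchar(df$molecule)))
    stop("blank molecule field at row ",
         which(!nzchar(df$molecule))[1], call. = FALSE)
  if ("target" %in% names(df) && !is.numeric(df$target))
    stop("column 'target' must be numeric", call. = FALSE)
  if (!"id" %in% names(df)) df$id <- as.character(seq_len(nrow(df)))
  if ("label" %in% names(df)) df$label <- .as_posneg(df$label)
  if (!is.null(theta)) {
    if (!"activity" %in% names(df))
      stop("theta given but no 'activity' column present", call. = FALSE)
    df$label <- ngn_label_by_threshold(df$activity, theta, direction)
  }
  df[, intersect(c("id", "molecule", "target", "activity", "label"),
                 names(df)), drop = FALSE]
}

#' Write a dataset table
#'
#' @param df Data frame with at least a `molecule` column.
#' @param path Output CSV path.
#' @export
ngn_write_dataset <- function(df, path) {
  stopifnot("molecule" %in% names(df))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load training control from a YAML or JSON configuration file
#'
#' Recognized fields mirror [ngn_control()] arguments plus `preset`; any
#' unspecified field takes the preset's value (default preset:
#' `"classification"`).  An empty file yields the full classification
#' defaults.  Out-of-range values raise a validation error naming the
#' field.
#'
#' @param path Path to a YAML (or JSON) document.
#' @return An [ngn_control()] object.
#' @export
ngn_load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("preset", "eta", "momentum", "rmse_threshold", "pretest_rmse",
             "max_epochs", "max_restarts", "hidden_size", "init_low",
             "init_high", "output_lo", "output_hi", "sharing_mode")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("validation error: unknown config field '", bad[1], "'",
         call. = FALSE)
  args <- cfg[intersect(names(cfg), known)]
  if (is.null(args$preset)) args$preset <- "classification"
  if (is.null(args$max_restarts)) args$max_restarts <- 3L
  if (is.null(args$output_lo)) args$output_lo <- 0.2
  if (is.null(args$output_hi)) args$output_hi <- 0.8
  if (is.null(args$sharing_mode)) args$sharing_mode <- "per_symbol_pair"
  do.call(ngn_control, args)
}

#' Save a fitted NGN (or library) to a portable model archive
#'
#' The archive is a versioned JSON document holding the serialized
#' grammar, the training control, and every weight layer (weights, biases
#' and momentum buffers at full precision) -- the complete accumulated
#' training state -- plus, for fitted models, the task metadata needed by
#' [predict.ngn()].
#'
#' @param object An `"ngn"` fit or an `ngn_library`.
#' @param path Output file path.
#' @export
ngn_save <- function(object, path) {
  lib <- if (inherits(object, "ngn")) object$library
         else if (inherits(object, "ngn_library")) object
         else stop("can only save 'ngn' fits or 'ngn_library' objects",
                   call. = FALSE)
  doc <- list(
    format = "ngn-model", version = 1L,
    grammar_name = lib$grammar$name,
    grammar = ngn_serialize_grammar(lib$grammar),
    control = unclass(lib$control),
    layers = lapply(lib$layers, function(l)
      list(dim = dim(l$w), w = as.vector(l$w), b = l$b,
           dw = as.vector(l$dw), db = l$db)))
  if (inherits(object, "ngn")) {
    doc$fit <- list(task = object$task, converged = object$converged,
                    epochs = object$epochs, restarts = object$restarts,
                    final_rmse = object$final_rmse,
                    target_range = object$target_range,
                    fitted = object$fitted.values, seed = object$seed)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model archive written by [ngn_save()]
#'
#' @param path Path to the archive.
#' @return An `"ngn"` fit (if the archive holds one) or an `ngn_library`.
#' @export
ngn_load <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "ngn-model"))
    stop("'", path, "' is not an ngn model archive", call. = FALSE)
  ctl <- doc$control
  control <- ngn_control(preset = ctl$preset, eta = ctl$eta,
                         momentum = ctl$momentum,
                         rmse_threshold = ctl$rmse_threshold,
                         pretest_rmse = ctl$pretest_rmse,
                         max_epochs = ctl$max_epochs,
                         max_restarts = ctl$max_restarts,
                         hidden_size = ctl$hidden_size,
                         init_low = ctl$init_low, init_high = ctl$init_high,
                         output_lo = ctl$output_lo, output_hi = ctl$output_hi,
                         sharing_mode = ctl$sharing_mode)
  g <- ngn_read_grammar(doc$grammar, name = doc$grammar_name)
  ks <- .library_keys(g, control$hidden_size, control$sharing_mode)
  layers <- lapply(doc$layers, function(l)
    list(w = matrix(l$w, l$dim[1], l$dim[2]), b = as.numeric(l$b),
         dw = matrix(l$dw, l$dim[1], l$dim[2]), db = as.numeric(l$db)))
  names(layers) <- names(doc$layers)
  stopifnot(identical(names(layers), ks$table$name))
  lib <- structure(list(grammar = g, keys = ks$table, lookup = ks$lookup,
                        layers = layers, control = control),
                   class = "ngn_library")
  if (is.null(doc$fit)) return(lib)
  f <- doc$fit
  structure(list(library = lib, grammar = g$name, control = control,
                 task = f$task, converged = f$converged, epochs = f$epochs,
                 restarts = f$restarts, final_rmse = f$final_rmse,
                 rmse_history = numeric(0), restart_at = integer(0),
                 target_range = f$target_range,
                 fitted.values = f$fitted, seed = f$seed,
                 call = quote(ngn_load())),
            class = "ngn")
}
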