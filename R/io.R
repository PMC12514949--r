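# Readers and writers for schemes, parameter sets and datasets (plain CSV /
# JSON with provenance headers), plus the command-line dispatcher.

provenance_header <- function(seed = NULL, config = NULL) {
  h <- sprintf("# vfadesign %s", as.character(packageVersion("vfadesign")))
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %d", as.integer(seed)))
  if (!is.null(config)) {
    hash <- sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 1e9
    h <- c(h, sprintf("# config-hash: %09d", hash))
  }
  h
}

write_with_header <- function(df, path, seed = NULL, config = NULL,
                              extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(provenance_header(seed, config), extra), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a flip-angle scheme to CSV
#'
#' Columns `index`, `time_s`, `flip_deg` (angles serialized with 4
#' decimals), preceded by a provenance comment header.
#'
#' @param scheme A [flip_scheme()].
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return The path, invisibly.
#' @export
write_scheme <- function(scheme, path, seed = NULL) {
  stopifnot(inherits(scheme, "flip_scheme"))
  df <- data.frame(index = seq_along(scheme$angles) - 1L,
                   time_s = scheme$times,
                   flip_deg = sprintf("%.4f", scheme$angles))
  write_with_header(df, path, seed, config = list(TR = scheme$TR))
}

#' Read a flip-angle scheme from CSV
#'
#' Expects columns `index`/`time_s`/`flip_deg`, a uniform time grid and
#' angles within \[0, 90\] degrees; malformed rows are reported with their
#' line number.
#'
#' @param path CSV path (comment lines starting with `#` are ignored).
#' @return A [flip_scheme()].
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  raw <- readLines(path)
  body_start <- which(!startsWith(raw, "#"))[1]
  df <- tryCatch(read.csv(path, comment.char = "#"),
                 error = function(e) stop("malformed scheme file ", path, ": ",
                                          conditionMessage(e)))
  need <- c("index", "time_s", "flip_deg")
  if (!all(need %in% names(df))) {
    stop("scheme file must have columns index, time_s, flip_deg")
  }
  line_of <- function(i) body_start + i  # header row + i-th data row
  bad <- which(!is.finite(df$flip_deg) | df$flip_deg < 0 | df$flip_deg > 90)
  if (length(bad)) {
    stop(sprintf("flip angle out of [0, 90] at line %d of %s (%.4f deg)",
                 line_of(bad[1]), path, df$flip_deg[bad[1]]))
  }
  if (nrow(df) > 1L) {
    dt <- diff(df$time_s)
    if (any(dt <= 0) || any(abs(dt - dt[1]) > 1e-6)) {
      bad_t <- which(abs(dt - dt[1]) > 1e-6 | dt <= 0)[1] + 1L
      stop(sprintf("non-uniform time grid at line %d of %s", line_of(bad_t),
                   path))
    }
    TR <- dt[1]
  } else {
    TR <- 1
  }
  flip_scheme(df$flip_deg, TR)
}

#' Write a kinetic parameter set to JSON
#'
#' @param params A [kin_params()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "kin_params"))
  x <- list(k = params$k, R1S = params$R1S, R1P = params$R1P, S0 = params$S0,
            P0 = params$P0)
  if (!is.null(params$B1S)) x$B1S <- params$B1S
  # I(17) significant digits: lossless round trip for doubles
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a kinetic parameter set from JSON
#'
#' @param path JSON file with keys `k`, `R1S`, `R1P`, `S0`, `P0` and
#'   optionally `B1S`.
#' @return A [kin_params()] object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("cannot parse parameter file ", path,
                                         ": ", conditionMessage(e)))
  need <- c("k", "R1S", "R1P", "S0", "P0")
  if (!all(need %in% names(x))) {
    stop("parameter file must define k, R1S, R1P, S0, P0: ", path)
  }
  kin_params(k = x$k, R1S = x$R1S, R1P = x$R1P, S0 = x$S0, P0 = x$P0,
             B1S = x$B1S)
}

#' Write a dynamic dataset to CSV
#'
#' Columns `time_s`, `substrate`, `product`, `flip_deg`, `included`; the
#' noise level and normalization divisor are stored in the comment header.
#'
#' @param dataset An `hp_dataset`.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return The path, invisibly.
#' @export
write_dataset <- function(dataset, path, seed = NULL) {
  stopifnot(inherits(dataset, "hp_dataset"))
  df <- data.frame(time_s = dataset$scheme$times,
                   substrate = dataset$signals[1, ],
                   product = dataset$signals[2, ],
                   flip_deg = sprintf("%.4f", dataset$scheme$angles),
                   included = dataset$included)
  extra <- c(sprintf("# sigma: %.17g %.17g", dataset$sigma[1],
                     dataset$sigma[2]),
             sprintf("# normalization: %.17g", dataset$normalization))
  write_with_header(df, path, seed, extra = extra)
}

#' Read a dynamic dataset from CSV
#'
#' @param path A CSV written by [write_dataset()] (or matching its layout).
#' @return An `hp_dataset`; generating parameters are not recoverable from
#'   file and are left `NULL`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  raw <- readLines(path)
  hdr <- raw[startsWith(raw, "#")]
  df <- read.csv(path, comment.char = "#")
  need <- c("time_s", "substrate", "product", "flip_deg", "included")
  if (!all(need %in% names(df))) {
    stop("dataset file must have columns time_s, substrate, product, ",
         "flip_deg, included: ", path)
  }
  TR <- if (nrow(df) > 1L) diff(df$time_s)[1] else 1
  scheme <- flip_scheme(df$flip_deg, TR)
  grab <- function(key, default) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(default)
    as.numeric(strsplit(sub(paste0("^# ", key, ": *"), "", ln[1]), " ")[[1]])
  }
  sigma <- grab("sigma", c(NA_real_, NA_real_))
  normalization <- grab("normalization", 1)
  structure(list(signals = rbind(substrate = df$substrate,
                                 product = df$product),
                 sigma = sigma, normalization = normalization,
                 included = as.logical(df$included), scheme = scheme,
                 params = NULL),
            class = "hp_dataset")
}

#' Write a collection of result objects to a directory
#'
#' Dispatches on object class (`flip_scheme`, `kin_params`, `hp_dataset`,
#' matrices, data frames) and writes each under a deterministic filename
#' derived from its name in `objects`.
#'
#' @param objects Named list of objects.
#' @param dir Output directory (must exist).
#' @param seed Optional seed recorded in provenance headers.
#' @return Character vector of the paths written, invisibly.
#' @export
write_results <- function(objects, dir, seed = NULL) {
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  stopifnot(is.list(objects), !is.null(names(objects)))
  paths <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    path <- if (inherits(obj, "flip_scheme")) {
      write_scheme(obj, file.path(dir, paste0(nm, ".csv")), seed)
    } else if (inherits(obj, "kin_params")) {
      write_params(obj, file.path(dir, paste0(nm, ".json")))
    } else if (inherits(obj, "hp_dataset")) {
      write_dataset(obj, file.path(dir, paste0(nm, ".csv")), seed)
    } else if (is.matrix(obj) && !is.null(colnames(obj))) {
      write_matrix_csv(obj, file.path(dir, paste0(nm, ".csv")))
    } else if (is.data.frame(obj)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      write.csv(obj, p, row.names = FALSE)
      p
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
      p
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}
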