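#' Tracer sets
#'
#' A tracer set names the biomarkers used by a mixing analysis and declares
#' their kind: fatty acid proportions (percent of total FA) or stable isotope
#' delta values (per mil).
#'
#' @param names Character vector of tracer identifiers (e.g. "16:1w7",
#'   "d13C"). Must be unique and non-empty.
#' @param kind Either "fa_proportion" or "si_delta".
#' @return An object of class \code{tracer_set}.
#' @export
tracer_set <- function(names, kind = c("fa_proportion", "si_delta")) {
  kind <- match.arg(kind)
  names <- as.character(names)
  if (length(names) == 0L) stop("tracer set must contain at least one tracer")
  if (anyDuplicated(names)) {
    stop("duplicate tracer names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  structure(list(names = names, kind = kind), class = "tracer_set")
}

#' @export
print.tracer_set <- function(x, ...) {
  cat(sprintf("<tracer_set: %d %s tracers>\n", length(x$names), x$kind))
  cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Normalize tracer spellings
#'
#' Applies a curated synonym map so that field data and library files written
#' with different conventions match by exact name: the Greek letters omega and
#' delta are replaced by their ASCII spellings ("18:3ω3" becomes
#' "18:3w3", "δ13C" becomes "d13C"), surrounding whitespace is dropped,
#' and the "n-x" notation for double-bond position is mapped to "wx".
#'
#' @param x Character vector of tracer names.
#' @return Character vector of harmonized names.
#' @export
harmonize_tracer_names <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("ω", "w", x)          # omega
  x <- gsub("Ω", "w", x)
  x <- gsub("δ", "d", x)          # delta
  x <- gsub("(\\d+:\\d+)n-?(\\d+)$", "\\1w\\2", x)
  x
}

#' Single biomarker profile
#'
#' One individual's tracer vector, labelled with its source group (for library
#' construction) or a consumer identifier.
#'
#' @param values Named numeric vector, one value per tracer.
#' @param label Group or consumer identifier.
#' @param kind Tracer kind, as in \code{\link{tracer_set}}.
#' @return An object of class \code{biomarker_profile}.
#' @export
biomarker_profile <- function(values, label,
                              kind = c("fa_proportion", "si_delta")) {
  kind <- match.arg(kind)
  if (is.null(names(values))) stop("profile values must be named by tracer")
  if (!is.numeric(values)) stop("profile values must be numeric")
  structure(list(values = values, label = as.character(label), kind = kind),
            class = "biomarker_profile")
}

#' Consumer-resource library
#'
#' Per-group, per-tracer mean and standard deviation of biomarker signatures.
#' For fatty acids the rows of \code{mean} are consumer percentages of total
#' FA measured in feeding trials, so trophic modification of dietary lipids is
#' already embedded in the library and no separate correction is applied.
#'
#' @param mean Numeric matrix, tracers in rows, source groups in columns.
#'   Dimnames are required and define the tracer and group order.
#' @param sd Non-negative matrix of the same shape.
#' @param kind Tracer kind.
#' @param raw_profiles Optional list of \code{biomarker_profile} objects the
#'   summary statistics were computed from (needed for resampling simulators).
#' @return An object of class \code{source_library}.
#' @export
source_library <- function(mean, sd, kind = c("fa_proportion", "si_delta"),
                           raw_profiles = NULL) {
  kind <- match.arg(kind)
  mean <- as.matrix(mean); sd <- as.matrix(sd)
  if (is.null(rownames(mean)) || is.null(colnames(mean)))
    stop("mean matrix needs tracer rownames and group colnames")
  if (!identical(dim(mean), dim(sd)))
    stop("mean and sd matrices must have identical shapes")
  if (is.null(dimnames(sd))) dimnames(sd) <- dimnames(mean)
  if (!identical(dimnames(mean), dimnames(sd)))
    stop("mean and sd dimnames disagree")
  if (anyDuplicated(colnames(mean)))
    stop("group names must be unique")
  neg <- which(sd < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative SD at tracer '%s', group '%s'",
                 rownames(sd)[neg[1, 1]], colnames(sd)[neg[1, 2]]))
  }
  structure(list(
    tracers = tracer_set(rownames(mean), kind),
    groups = colnames(mean),
    mean = mean, sd = sd,
    raw_profiles = raw_profiles
  ), class = "source_library")
}

#' @export
print.source_library <- function(x, ...) {
  cat(sprintf("<source_library: %d groups x %d %s tracers>\n",
              length(x$groups), length(x$tracers$names), x$tracers$kind))
  cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  if (!is.null(x$raw_profiles))
    cat(sprintf("  raw profiles: %d\n", length(x$raw_profiles)))
  invisible(x)
}

#' Trophic fractionation specification
#'
#' Mean shift and its standard deviation applied to each tracer during trophic
#' transfer. Given as vectors (one value per tracer, shared across source
#' groups) or matrices (tracer x group). For fatty-acid libraries built from
#' feeding trials, fractionation is already embedded and both default to zero.
#'
#' @param mean Numeric vector or matrix of mean fractionation per tracer.
#' @param sd Non-negative vector or matrix of fractionation SDs.
#' @return An object of class \code{fractionation_spec}.
#' @export
fractionation_spec <- function(mean, sd) {
  if (any(sd < 0)) stop("fractionation SD must be non-negative")
  if (is.matrix(mean) != is.matrix(sd))
    stop("mean and sd must both be vectors or both matrices")
  if (is.matrix(mean)) {
    if (!identical(dim(mean), dim(sd))) stop("dimension mismatch")
  } else if (length(mean) != length(sd)) {
    stop("mean and sd must have equal length")
  }
  structure(list(mean = mean, sd = sd), class = "fractionation_spec")
}

#' Zero fractionation for a library
#' @param lib A \code{source_library}.
#' @return A \code{fractionation_spec} with all means and SDs zero.
#' @export
zero_fractionation <- function(lib) {
  J <- length(lib$tracers$names)
  z <- stats::setNames(numeric(J), lib$tracers$names)
  fractionation_spec(z, z)
}

# Expand a fractionation spec to tracer x group matrices aligned with a
# library; vector input is broadcast across groups.
.frac_matrices <- function(frac, lib) {
  J <- length(lib$tracers$names); K <- length(lib$groups)
  dn <- list(lib$tracers$names, lib$groups)
  if (is.null(frac)) {
    return(list(f = matrix(0, J, K, dimnames = dn),
                g = matrix(0, J, K, dimnames = dn)))
  }
  to_mat <- function(v) {
    if (is.matrix(v)) {
      if (!identical(dim(v), c(J, K)))
        stop("fractionation matrix shape does not match library")
      m <- v
      if (!is.null(rownames(m))) m <- m[lib$tracers$names, lib$groups, drop = FALSE]
      dimnames(m) <- dn
      m
    } else {
      if (length(v) != J) stop("fractionation vector length does not match tracer count")
      if (!is.null(names(v))) v <- v[lib$tracers$names]
      matrix(v, J, K, dimnames = dn)
    }
  }
  list(f = to_mat(frac$mean), g = to_mat(frac$sd))
}

#' Read a consumer-resource library from CSV
#'
#' The canonical dialect is long form with columns \code{group}, \code{tracer},
#' \code{mean}, \code{sd}; one row per (group, tracer) cell. A wide dialect is
#' accepted with \code{format = "wide"}: columns \code{group}, \code{stat}
#' (\code{"mean"} or \code{"sd"}) followed by one column per tracer. Tracer
#' order is preserved from the file (long form: order of first appearance).
#'
#' @param path CSV file path (UTF-8, "." decimal).
#' @param kind Tracer kind of the library.
#' @param format "long" (default) or "wide".
#' @return A \code{source_library}.
#' @export
read_source_library <- function(path, kind = c("fa_proportion", "si_delta"),
                                format = c("long", "wide")) {
  kind <- match.arg(kind); format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                       fileEncoding = "UTF-8")
  if (format == "long") {
    need <- c("group", "tracer", "mean", "sd")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("format error: missing column(s) ", paste(miss, collapse = ", "))
    d$tracer <- harmonize_tracer_names(d$tracer)
    if (anyDuplicated(d[c("group", "tracer")])) {
      dup <- d[duplicated(d[c("group", "tracer")]), c("group", "tracer")][1, ]
      stop(sprintf("duplicate entry for group '%s', tracer '%s'",
                   dup$group, dup$tracer))
    }
    neg <- which(d$sd < 0)
    if (length(neg))
      stop(sprintf("negative SD at tracer '%s', group '%s'",
                   d$tracer[neg[1]], d$group[neg[1]]))
    tr <- unique(d$tracer); gr <- unique(d$group)
    m <- matrix(NA_real_, length(tr), length(gr), dimnames = list(tr, gr))
    s <- m
    m[cbind(d$tracer, d$group)] <- d$mean
    s[cbind(d$tracer, d$group)] <- d$sd
    if (anyNA(m)) stop("incomplete library: some (group, tracer) cells missing")
    source_library(m, s, kind)
  } else {
    need <- c("group", "stat")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("format error: missing column(s) ", paste(miss, collapse = ", "))
    tr <- harmonize_tracer_names(setdiff(names(d), need))
    names(d) <- c(need, tr)[match(names(d), c(need, setdiff(names(d), need)))]
    gr <- unique(d$group)
    pick <- function(stat) {
      sub <- d[d$stat == stat, , drop = FALSE]
      if (anyDuplicated(sub$group))
        stop(sprintf("duplicate entry for group '%s' (%s rows)",
                     sub$group[duplicated(sub$group)][1], stat))
      if (!setequal(sub$group, gr)) stop("format error: missing ", stat, " rows")
      m <- t(as.matrix(sub[, tr, drop = FALSE]))
      colnames(m) <- sub$group
      m[, gr, drop = FALSE]
    }
    m <- pick("mean"); s <- pick("sd")
    neg <- which(s < 0, arr.ind = TRUE)
    if (nrow(neg))
      stop(sprintf("negative SD at tracer '%s', group '%s'",
                   rownames(s)[neg[1, 1]], colnames(s)[neg[1, 2]]))
    source_library(m, s, kind)
  }
}

#' Write a consumer-resource library to CSV
#'
#' @param lib A \code{source_library}.
#' @param path Output path.
#' @param format "long" or "wide" (see \code{\link{read_source_library}}).
#' @return \code{path}, invisibly.
#' @export
write_source_library <- function(lib, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "long") {
    d <- data.frame(
      group = rep(lib$groups, each = nrow(lib$mean)),
      tracer = rep(rownames(lib$mean), times = length(lib$groups)),
      mean = as.vector(lib$mean),
      sd = as.vector(lib$sd),
      stringsAsFactors = FALSE
    )
  } else {
    d <- rbind(
      data.frame(group = lib$groups, stat = "mean", t(lib$mean),
                 check.names = FALSE, stringsAsFactors = FALSE),
      data.frame(group = lib$groups, stat = "sd", t(lib$sd),
                 check.names = FALSE, stringsAsFactors = FALSE)
    )
  }
  utils::write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' Packaged lake phytoplankton stable isotope library
#'
#' Published within-lake means and SDs of bulk d13C and d15N for the three
#' major phytoplankton groups (diatoms, chlorophytes, cyanobacteria), derived
#' from the multi-lake survey of Vuorio et al. (2006, Freshwater Biology 51).
#' Normalization removed between-lake variability, so the SDs reflect
#' within-lake variation only. The companion fractionation specification has
#' zero mean shift and SDs of 1.3 permil (d13C) and 1.0 permil (d15N),
#' representing uncertainty in consumer trophic fractionation.
#'
#' @return A list with elements \code{library} (\code{source_library}) and
#'   \code{fractionation} (\code{fractionation_spec}).
#' @export
phytoplankton_si_library <- function() {
  path <- system.file("extdata", "phytoplankton_si_library.csv",
                      package = "famix", mustWork = TRUE)
  lib <- read_source_library(path, kind = "si_delta", format = "long")
  frac <- fractionation_spec(
    mean = stats::setNames(c(0, 0), lib$tracers$names),
    sd = stats::setNames(c(1.3, 1.0), lib$tracers$names)
  )
  list(library = lib, fractionation = frac)
}

#' Summarize individual profiles into a library
#'
#' Builds the per-group mean and sample standard deviation (n - 1 denominator)
#' of each tracer from individual feeding-trial profiles, retaining the raw
#' profiles for resampling-based simulation.
#'
#' @param profiles List of \code{biomarker_profile} objects; the label of each
#'   profile is its diet group.
#' @return A \code{source_library} with \code{raw_profiles} set.
#' @export
summarize_profiles <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles supplied")
  kind <- profiles[[1]]$kind
  tr <- names(profiles[[1]]$values)
  for (p in profiles) {
    if (!identical(names(p$values), tr))
      stop("mismatched tracer sets across profiles")
    if (!identical(p$kind, kind)) stop("mixed tracer kinds across profiles")
  }
  labs <- vapply(profiles, function(p) p$label, character(1))
  groups <- unique(labs)
  m <- matrix(NA_real_, length(tr), length(groups),
              dimnames = list(tr, groups))
  s <- m
  for (g in groups) {
    vals <- do.call(rbind, lapply(profiles[labs == g], function(p) p$values))
    m[, g] <- colMeans(vals)
    if (nrow(vals) == 1L) {
      warning(sprintf("group '%s' has a single profile; SD recorded as 0", g))
      s[, g] <- 0
    } else {
      s[, g] <- apply(vals, 2, stats::sd)
    }
  }
  source_library(m, s, kind, raw_profiles = profiles)
}

#' Z-score normality diagnostic for dominant fatty acids
#'
#' Selects the fatty acids whose grand mean across all profiles exceeds an
#' abundance threshold (default 5 percent of total FA), z-scores each selected
#' tracer within its diet group, and pools the z-scores. An approximately
#' normal pooled distribution (SD near 1, median near 0) supports the Gaussian
#' likelihood used by the mixing model for proportion data.
#'
#' @param profiles List of \code{biomarker_profile} objects (FA kind).
#' @param abundance_threshold Grand-mean percentage a tracer must exceed to be
#'   included. Default 5.
#' @return A list of class \code{zscore_summary} with \code{pooled_sd},
#'   \code{pooled_median}, \code{per_tracer_stats} (mean, sd, skew of the
#'   pooled z-scores per tracer), \code{tracers_included} and the pooled
#'   \code{z} values.
#' @export
zscore_diagnostic <- function(profiles, abundance_threshold = 5.0) {
  if (length(profiles) == 0L) stop("no profiles supplied")
  if (profiles[[1]]$kind != "fa_proportion")
    stop("z-score diagnostic applies to fatty-acid proportion data")
  vals <- do.call(rbind, lapply(profiles, function(p) p$values))
  labs <- vapply(profiles, function(p) p$label, character(1))
  grand <- colMeans(vals)
  keep <- names(grand)[grand > abundance_threshold]
  if (length(keep) == 0L)
    stop("no tracer exceeds the abundance threshold of ", abundance_threshold)
  zs <- vector("list", length(keep)); names(zs) <- keep
  for (tr in keep) {
    z <- numeric(0)
    for (g in unique(labs)) {
      v <- vals[labs == g, tr]
      z <- c(z, if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v)
             else rep(0, length(v)))
    }
    zs[[tr]] <- z
  }
  skew <- function(z) if (stats::sd(z) > 0)
    mean((z - mean(z))^3) / stats::sd(z)^3 else 0
  per <- data.frame(
    tracer = keep,
    mean = vapply(zs, mean, numeric(1)),
    sd = vapply(zs, stats::sd, numeric(1)),
    skew = vapply(zs, skew, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  pooled <- unlist(zs, use.names = FALSE)
  structure(list(
    pooled_sd = stats::sd(pooled),
    pooled_median = stats::median(pooled),
    per_tracer_stats = per,
    tracers_included = keep,
    z = pooled
  ), class = "zscore_summary")
}

#' Validate a consumer-resource library
#'
#' Checks library invariants and reports every violation with its location
#' rather than stopping at the first: non-negative SDs, consistent shapes,
#' unique group names, and for fatty-acid libraries closure of the per-group
#' mean vectors (sum within \code{closure_tol} of \code{closure_total}).
#'
#' @param lib A \code{source_library}.
#' @param closure_total Declared profile total for FA libraries. Default 100.
#' @param closure_tol Allowed deviation from the total. Default 5.
#' @return A data.frame with columns \code{location} and \code{message}; zero
#'   rows when the library is valid.
#' @export
validate_library <- function(lib, closure_total = 100, closure_tol = 5) {
  out <- list()
  add <- function(location, message)
    out[[length(out) + 1L]] <<- data.frame(location = location,
                                           message = message,
                                           stringsAsFactors = FALSE)
  if (!identical(dim(lib$mean), dim(lib$sd)))
    add("sd", "sd matrix shape differs from mean matrix")
  neg <- which(lib$sd < 0, arr.ind = TRUE)
  for (i in seq_len(nrow(neg))) {
    add(sprintf("sd[%s,%s]", rownames(lib$sd)[neg[i, 1]],
                colnames(lib$sd)[neg[i, 2]]),
        "negative standard deviation")
  }
  if (anyDuplicated(lib$groups)) add("groups", "duplicate group names")
  if (lib$tracers$kind == "fa_proportion") {
    negm <- which(lib$mean < 0, arr.ind = TRUE)
    for (i in seq_len(nrow(negm))) {
      add(sprintf("mean[%s,%s]", rownames(lib$mean)[negm[i, 1]],
                  colnames(lib$mean)[negm[i, 2]]),
          "negative FA proportion")
    }
    tot <- colSums(lib$mean)
    for (g in names(tot)[abs(tot - closure_total) > closure_tol]) {
      add(sprintf("group %s", g),
          sprintf("mean profile sums to %.2f, outside %g +/- %g",
                  tot[g], closure_total, closure_tol))
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(location = character(0), message = character(0),
                  stringsAsFactors = FALSE)
}

#' Read consumer observations from CSV
#'
#' One row per individual consumer; an optional \code{id} column plus one
#' column per tracer. Tracer columns are matched to the library by exact name
#' after \code{\link{harmonize_tracer_names}}.
#'
#' @param path CSV file path.
#' @param lib Optional \code{source_library}; when given, the returned matrix
#'   is reordered to the library's tracer order and missing tracers are an
#'   error.
#' @return Numeric matrix, one row per consumer, tracer columns; row names are
#'   consumer ids.
#' @export
read_consumers <- function(path, lib = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                       fileEncoding = "UTF-8")
  ids <- if ("id" %in% names(d)) as.character(d$id) else
    as.character(seq_len(nrow(d)))
  d <- d[, setdiff(names(d), "id"), drop = FALSE]
  names(d) <- harmonize_tracer_names(names(d))
  x <- as.matrix(d)
  rownames(x) <- ids
  if (!is.null(lib)) {
    miss <- setdiff(lib$tracers$names, colnames(x))
    if (length(miss))
      stop("consumer file is missing tracer(s): ", paste(miss, collapse = ", "))
    x <- x[, lib$tracers$names, drop = FALSE]
  }
  if (!is.numeric(x)) stop("non-numeric consumer values")
  x
}

#' Write consumer observations to CSV
#' @param x Consumer matrix (rows = consumers, columns = tracers).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_consumers <- function(x, path) {
  d <- data.frame(id = rownames(x) %||% seq_len(nrow(x)), x,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' Read a fractionation table from CSV
#'
#' Columns \code{tracer}, \code{mean}, \code{sd}; one row per tracer.
#'
#' @param path CSV file path.
#' @return A \code{fractionation_spec} with named vectors.
#' @export
read_fractionation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("tracer", "mean", "sd")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  tr <- harmonize_tracer_names(d$tracer)
  fractionation_spec(stats::setNames(d$mean, tr), stats::setNames(d$sd, tr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
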