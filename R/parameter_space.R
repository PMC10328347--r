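#' Define a single simulator parameter
#'
#' A parameter is either sampled (role \code{"free"} or
#' \code{"hm-constrained"}, with lower/upper bounds in its native units) or
#' held at a single value (role \code{"fixed"} or \code{"data-derived"}).
#' History-matching-constrained parameters carry explicit fallback bounds;
#' their effective range is narrowed later by the plausible region of a
#' history-matching wave.
#'
#' @param name parameter name, unique within a space.
#' @param role one of \code{"free"}, \code{"fixed"}, \code{"data-derived"},
#'   \code{"hm-constrained"}.
#' @param bounds numeric length-2 \code{c(lower, upper)} for sampled roles.
#' @param value single numeric for fixed/data-derived roles.
#' @param unit unit string (informational, e.g. \code{"ms"}, \code{"mm/ms"}).
#' @param submodel which simulator component the parameter belongs to, one of
#'   \code{"tissue-ep"}, \code{"ventricular-cell"}, \code{"atrial-cell"},
#'   \code{"passive"}, \code{"circulation"}, \code{"boundary"}.
#' @return an object of class \code{"param_def"}.
#' @export
param_def <- function(name, role = c("free", "fixed", "data-derived",
                                     "hm-constrained"),
                      bounds = NULL, value = NULL, unit = "",
                      submodel = "") {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  sampled <- role %in% c("free", "hm-constrained")
  if (sampled) {
    if (is.null(bounds) || length(bounds) != 2L || anyNA(bounds))
      stop(sprintf("parameter '%s': role '%s' requires bounds c(lower, upper)",
                   name, role))
    bounds <- as.numeric(bounds)
    if (bounds[1] >= bounds[2])
      stop(sprintf("parameter '%s': inverted or empty bounds (%g, %g)",
                   name, bounds[1], bounds[2]))
    if (!is.null(value))
      stop(sprintf("parameter '%s': sampled roles take bounds, not a value",
                   name))
  } else {
    if (is.null(value) || length(value) != 1L || is.na(value))
      stop(sprintf("parameter '%s': role '%s' requires a single value",
                   name, role))
    value <- as.numeric(value)
    if (!is.null(bounds))
      stop(sprintf("parameter '%s': fixed roles take a value, not bounds",
                   name))
  }
  structure(list(name = name, role = role, bounds = bounds, value = value,
                 unit = unit, submodel = submodel),
            class = "param_def")
}

#' Assemble a parameter space
#'
#' Collects parameter definitions into an ordered sampling domain. The free
#' dimension count \code{D} counts \code{free} and \code{hm-constrained}
#' parameters; the ordering of parameters is stable and shared by every
#' design generated from the space.
#'
#' @param params list of \code{\link{param_def}} objects.
#' @return object of class \code{"parameter_space"} with elements
#'   \code{params}, \code{D}, \code{free} (names), \code{bounds}
#'   (D x 2 matrix) and \code{fixed} (named vector of held values).
#' @export
parameter_space <- function(params) {
  if (inherits(params, "param_def")) params <- list(params)
  stopifnot(length(params) >= 1L)
  ok <- vapply(params, inherits, logical(1), "param_def")
  if (!all(ok)) stop("all elements must be param_def objects")
  nm <- vapply(params, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate parameter names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  roles <- vapply(params, `[[`, character(1), "role")
  sampled <- roles %in% c("free", "hm-constrained")
  bounds <- NULL
  if (any(sampled)) {
    bounds <- t(vapply(params[sampled], `[[`, numeric(2), "bounds"))
    dimnames(bounds) <- list(nm[sampled], c("lower", "upper"))
  }
  fixed <- vapply(params[!sampled], `[[`, numeric(1), "value")
  names(fixed) <- nm[!sampled]
  structure(list(params = params, D = sum(sampled), free = nm[sampled],
                 bounds = bounds, fixed = fixed),
            class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat(sprintf("Parameter space: %d parameters (%d sampled, %d held fixed)\n",
              length(x$params), x$D, length(x$fixed)))
  if (x$D > 0) {
    cat("Sampled dimensions:\n")
    for (nm in x$free) {
      b <- x$bounds[nm, ]
      p <- x$params[[match(nm, vapply(x$params, `[[`, character(1), "name"))]]
      cat(sprintf("  %-14s [%g, %g] %s (%s)\n", nm, b[1], b[2], p$unit,
                  p$role))
    }
  }
  invisible(x)
}

#' Load a parameter table from YAML or JSON
#'
#' The config mirrors the columns of a simulator parameter table: each entry
#' has \code{name}, a \code{range} (two numbers) or \code{value} (one
#' number), and optional \code{unit}, \code{role}, \code{submodel}. When
#' \code{role} is omitted it is inferred: entries with a \code{range} are
#' free, entries with a \code{value} are fixed.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a \code{\link{parameter_space}}.
#' @export
load_parameter_table <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = FALSE)
         else stop("unsupported config format: ", ext)
  entries <- if (!is.null(raw$parameters)) raw$parameters else raw
  defs <- lapply(entries, function(e) {
    if (is.null(e$name)) stop("config entry without a name")
    role <- e$role
    if (is.null(role))
      role <- if (!is.null(e$range)) "free" else "fixed"
    if (!role %in% c("free", "fixed", "data-derived", "hm-constrained"))
      stop(sprintf("parameter '%s': unknown role '%s'", e$name, role))
    param_def(e$name, role = role,
              bounds = if (!is.null(e$range)) unlist(e$range),
              value = e$value,
              unit = if (is.null(e$unit)) "" else e$unit,
              submodel = if (is.null(e$submodel)) "" else e$submodel)
  })
  parameter_space(defs)
}

## ---- unit-box scaling -------------------------------------------------

#' Rescale between native units and the unit box
#'
#' @param space a \code{\link{parameter_space}}.
#' @param X matrix (rows = points) in native units (\code{scale_to_unit}) or
#'   in the unit box (\code{scale_from_unit}); columns follow the space's
#'   sampled-parameter order.
#' @return matrix of the same shape.
#' @export
scale_to_unit <- function(space, X) {
  X <- as_design_matrix(X, space)
  lo <- space$bounds[, 1]; hi <- space$bounds[, 2]
  sweep(sweep(X, 2, lo, "-"), 2, hi - lo, "/")
}

#' @rdname scale_to_unit
#' @export
scale_from_unit <- function(space, X) {
  X <- as_design_matrix(X, space)
  lo <- space$bounds[, 1]; hi <- space$bounds[, 2]
  sweep(sweep(X, 2, hi - lo, "*"), 2, lo, "+")
}

as_design_matrix <- function(X, space = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (!is.null(space)) {
    if (ncol(X) != space$D)
      stop(sprintf("design has %d columns, space has %d sampled dimensions",
                   ncol(X), space$D))
    if (is.null(colnames(X))) colnames(X) <- space$free
  }
  X
}

new_design <- function(values, space, kind, seed) {
  colnames(values) <- space$free
  structure(values, space = space, kind = kind, seed = seed,
            class = c("design_matrix", class(values)))
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d x %d, kind = %s, seed = %s\n",
              nrow(x), ncol(x), attr(x, "kind"),
              format(attr(x, "seed"))))
  print(utils::head(unclass(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

## ---- designs ----------------------------------------------------------

#' Latin hypercube design over a parameter space
#'
#' Draws a maximin-free random Latin hypercube in the unit box (one point per
#' equal-width stratum in every dimension) and rescales it to the space's
#' bounds. Reproducible for a fixed seed.
#'
#' @param space a \code{\link{parameter_space}}.
#' @param n number of design points (>= 1).
#' @param seed integer seed (mandatory).
#' @return \code{n x D} design matrix in native units.
#' @export
latin_hypercube <- function(space, n, seed) {
  stopifnot(inherits(space, "parameter_space"), space$D >= 1)
  if (n < 1) stop("n must be >= 1")
  U <- with_seed(seed, lhs::randomLHS(n, space$D))
  new_design(scale_from_unit(space, U), space, "lhs", seed)
}

#' Saltelli design for total-effect estimation
#'
#' Builds the radial block structure used by Saltelli-type estimators: two
#' independent Latin hypercube half-matrices A and B of \code{n_base} rows
#' each, plus D matrices AB_i equal to A with column i replaced by B's
#' column i. Rows are stacked as \code{[A; B; AB_1; ...; AB_D]}, giving
#' \code{n_base * (D + 2)} rows; \code{\link{saltelli_blocks}} recovers the
#' blocks from the flat matrix.
#'
#' @inheritParams latin_hypercube
#' @param n_base base sample size per block (>= 2).
#' @return design matrix with attributes \code{n_base} and block layout.
#' @export
saltelli_design <- function(space, n_base, seed) {
  stopifnot(inherits(space, "parameter_space"), space$D >= 1)
  if (n_base < 2) stop("n_base must be >= 2")
  D <- space$D
  U <- with_seed(seed, {
    A <- lhs::randomLHS(n_base, D)
    B <- lhs::randomLHS(n_base, D)
    blocks <- vector("list", D + 2L)
    blocks[[1]] <- A; blocks[[2]] <- B
    for (i in seq_len(D)) {
      ABi <- A
      ABi[, i] <- B[, i]
      blocks[[i + 2L]] <- ABi
    }
    do.call(rbind, blocks)
  })
  d <- new_design(scale_from_unit(space, U), space, "saltelli", seed)
  attr(d, "n_base") <- as.integer(n_base)
  d
}

#' Split a Saltelli design into its A, B and AB_i blocks
#'
#' @param design a design produced by \code{\link{saltelli_design}}, or any
#'   matrix with the same stacking given \code{n_base}.
#' @param n_base base sample size; taken from the design attribute if absent.
#' @return list with elements \code{A}, \code{B} and \code{AB} (a list of D
#'   matrices).
#' @export
saltelli_blocks <- function(design, n_base = attr(design, "n_base")) {
  if (is.null(n_base)) stop("n_base not given and not stored on the design")
  n_base <- as.integer(n_base)
  X <- unclass(design)
  attr(X, "space") <- NULL; attr(X, "kind") <- NULL; attr(X, "seed") <- NULL
  attr(X, "n_base") <- NULL
  D <- nrow(X) / n_base - 2L
  if (D < 1 || nrow(X) != n_base * (D + 2L))
    stop("row count is not n_base * (D + 2)")
  idx <- function(k) ((k - 1L) * n_base + 1L):(k * n_base)
  list(A = X[idx(1L), , drop = FALSE],
       B = X[idx(2L), , drop = FALSE],
       AB = lapply(seq_len(D), function(i) X[idx(i + 2L), , drop = FALSE]))
}

#' Greedy maximin space-filling subsample
#'
#' Selects \code{n} rows of a candidate cloud by farthest-point traversal in
#' the unit-scaled box: the seeded start point is drawn at random, then each
#' further point maximises the minimum distance to the points already chosen
#' (ties broken by the seeded random ordering). Used to extract a uniform
#' subset from an irregular plausible region.
#'
#' @param cloud design matrix (rows = candidate points) carrying its space,
#'   or a plain matrix plus \code{space}.
#' @param n subset size (<= rows of cloud).
#' @param seed integer seed; picks the start point and breaks ties.
#' @param space parameter space used for unit scaling (defaults to the
#'   cloud's own).
#' @return \code{n x D} design matrix (kind \code{"subset"}).
#' @export
subsample_space_filling <- function(cloud, n, seed,
                                    space = attr(cloud, "space")) {
  X <- as_design_matrix(cloud, space)
  if (n > nrow(X)) stop("n exceeds the cloud size")
  U <- if (!is.null(space)) scale_to_unit(space, X) else X
  ord <- with_seed(seed, sample.int(nrow(U)))  # start point + tie order
  U <- U[ord, , drop = FALSE]
  X <- X[ord, , drop = FALSE]
  chosen <- integer(n)
  chosen[1] <- 1L
  if (n > 1) {
    d2 <- rowSums(sweep(U, 2, U[1L, ], "-")^2)
    for (k in 2:n) {
      j <- which.max(d2)   # first index wins ties -> seeded order decides
      chosen[k] <- j
      nd <- rowSums(sweep(U, 2, U[j, ], "-")^2)
      d2 <- pmin(d2, nd)
    }
  }
  out <- X[chosen, , drop = FALSE]
  if (!is.null(space)) new_design(out, space, "subset", seed) else out
}

## ---- patient-derived constants ----------------------------------------

#' Patient-derived circulation constants
#'
#' Worked-example computations that turn routine clinical measurements into
#' lumped-circulation parameters: the reference systemic flow is the stroke
#' volume over the beat duration, the heart rate is the reciprocal of the
#' basic cycle length, and a tube wall area follows from the adjacent valve
#' orifice area assuming a circular cross-section and a given wall
#' thickness.
#'
#' @param sv_ml stroke volume (mL).
#' @param bcl_ms basic cycle length (ms).
#' @return \code{derive_qref}: systemic flow in mL/s; \code{derive_hr}:
#'   heart rate in beats per minute; \code{tube_wall_area}: annular wall
#'   area in mm^2.
#' @export
derive_qref <- function(sv_ml, bcl_ms) {
  stopifnot(sv_ml > 0, bcl_ms > 0)
  sv_ml / (bcl_ms / 1000)
}

#' @rdname derive_qref
#' @export
derive_hr <- function(bcl_ms) {
  stopifnot(bcl_ms > 0)
  60000 / bcl_ms
}

#' @rdname derive_qref
#' @param orifice_area_mm2 open orifice area of the adjacent valve (mm^2).
#' @param wall_thickness_mm wall thickness (mm): 2 for arteries, 1 for veins.
#' @export
tube_wall_area <- function(orifice_area_mm2, wall_thickness_mm) {
  stopifnot(orifice_area_mm2 > 0, wall_thickness_mm > 0)
  r <- sqrt(orifice_area_mm2 / pi)
  pi * ((r + wall_thickness_mm)^2 - r^2)
}

## ---- misc -------------------------------------------------------------

# Run an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
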