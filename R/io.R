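# I/O: XYZ / extended-XYZ geometries and trajectories, JSON archives for
# models and training sets. Archives are plain text, self-describing and
# versioned; numeric arrays round-trip at full double precision (17
# significant digits).

ARCHIVE_VERSION <- "1"

#' Read / write XYZ and extended-XYZ files
#'
#' The extended-XYZ comment line carries `key=value` metadata (e.g.
#' `energy=-76.02`); with `forces = TRUE`, per-atom force columns 5-7
#' (Ha/angstrom) are written after the coordinates.
#'
#' @param path file path.
#' @param charge,multiplicity passed to [geometry()].
#' @return `read_xyz`: a [geometry()] (with attribute `comment` and, if
#'   present, `energy` and `forces`); `write_xyz`: `path`, invisibly.
#' @export
read_xyz <- function(path, charge = 0L, multiplicity = 1L) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1]))
  comment <- if (length(ln) >= 2) ln[2] else ""
  rows <- strsplit(trimws(ln[3:(2 + n)]), "\\s+")
  sym <- vapply(rows, `[`, "", 1)
  pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  g <- geometry(sym, pos, charge = charge, multiplicity = multiplicity)
  attr(g, "comment") <- comment
  kv <- parse_extxyz_comment(comment)
  if (!is.null(kv$energy)) attr(g, "energy") <- as.numeric(kv$energy)
  if (length(rows[[1]]) >= 7) {
    attr(g, "forces") <- t(vapply(rows, function(r) as.numeric(r[5:7]),
                                  numeric(3)))
  }
  g
}

parse_extxyz_comment <- function(s) {
  out <- list()
  for (tok in regmatches(s, gregexpr('[A-Za-z_]+="[^"]*"|[A-Za-z_]+=\\S+',
                                     s))[[1]]) {
    eq <- regexpr("=", tok)
    key <- substr(tok, 1, eq - 1)
    val <- gsub('^"|"$', "", substr(tok, eq + 1, nchar(tok)))
    out[[key]] <- val
  }
  out
}

#' @rdname read_xyz
#' @param g a [geometry()].
#' @param comment comment line or named list serialized as `key=value`.
#' @param energy optional energy (Ha) added to the comment line.
#' @param forces optional n x 3 matrix written as extra columns.
#' @param append append as an additional frame (trajectory files).
#' @export
write_xyz <- function(g, path, comment = "", energy = NULL, forces = NULL,
                      append = FALSE) {
  if (is.list(comment))
    comment <- paste(vapply(names(comment), function(k)
      paste0(k, "=", comment[[k]]), ""), collapse = " ")
  if (!is.null(energy))
    comment <- trimws(paste0(comment, " energy=",
                             format(energy, digits = 17)))
  lines <- c(as.character(length(g$Z)), comment)
  for (i in seq_along(g$Z)) {
    row <- sprintf("%-3s % .10f % .10f % .10f", g$symbols[i],
                   g$positions[i, 1], g$positions[i, 2], g$positions[i, 3])
    if (!is.null(forces))
      row <- paste0(row, sprintf(" % .10e % .10e % .10e",
                                 forces[i, 1], forces[i, 2], forces[i, 3]))
    lines <- c(lines, row)
  }
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory as multi-frame extended-XYZ
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  first <- TRUE
  for (s in traj$states) {
    g <- with_positions(traj$geometry, s$positions)
    write_xyz(g, path,
              comment = list(time_fs = s$time,
                             epot = format(s$epot, digits = 17),
                             ekin = format(s$ekin, digits = 17)),
              forces = s$forces, append = !first)
    first <- FALSE
  }
  invisible(path)
}

num_full <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

geometry_to_list <- function(g) {
  list(symbols = g$symbols, positions = g$positions, charge = g$charge,
       multiplicity = g$multiplicity)
}
geometry_from_list <- function(l) {
  p <- l$positions
  pos <- if (is.list(p)) do.call(rbind, lapply(p, unlist)) else as.matrix(p)
  geometry(unlist(l$symbols), pos,
           charge = as.integer(l$charge),
           multiplicity = as.integer(l$multiplicity))
}

#' Save / load a fitted model stack
#'
#' JSON archive containing the KRR state (training features and weights),
#' any delta-models, the kernel and method specs, the reference geometry and
#' a format version. Loading refuses archives whose version or basis
#' metadata do not match; a loaded stack predicts bit-identically to the
#' saved one.
#'
#' @param stack a [model_stack()] (or bare `gamma_model`).
#' @param path file path (`.json`).
#' @return `save_model`: `path`, invisibly. `load_model`: a `model_stack`.
#' @export
save_model <- function(stack, path) {
  if (inherits(stack, "gamma_model")) stack <- model_stack(stack)
  gm <- stack$gamma
  obj <- list(
    format = "rdmlearn-model", version = ARCHIVE_VERSION,
    flavor = stack$flavor,
    kernel = gm$kernel[c("kind", "alpha", "gamma_scale", "degree", "offset")],
    method = gm$method[c("functional", "basis", "scf_convergence")],
    M = gm$M, n_train = gm$n_train,
    ref = geometry_to_list(gm$ref),
    X = gm$X, B = gm$B)
  if (!is.null(stack$delta_refine))
    obj$delta_refine <- stack$delta_refine[c("W", "b", "target_kind")]
  if (!is.null(stack$delta_props)) {
    obj$delta_props <- lapply(stack$delta_props, function(dm)
      dm[c("W", "b", "target_kind")])
  }
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "rdmlearn-model"))
    stop("not a model archive: ", path)
  if (!identical(as.character(obj$version), ARCHIVE_VERSION))
    stop("archive version mismatch: ", obj$version)
  ref <- geometry_from_list(obj$ref)
  method <- method_spec(obj$method$functional, obj$method$basis,
                        obj$method$scf_convergence)
  if (basis_dimension(ref, method$basis) != obj$M)
    stop("archive refused: basis label inconsistent with stored dimension M")
  kk <- kernel_spec(obj$kernel$kind, alpha = obj$kernel$alpha,
                    gamma_scale = obj$kernel$gamma_scale,
                    degree = obj$kernel$degree, offset = obj$kernel$offset)
  gm <- structure(list(X = as.matrix(obj$X), B = as.matrix(obj$B),
                       kernel = kk, ref = ref, method = method,
                       M = as.integer(obj$M),
                       n_train = as.integer(obj$n_train)),
                  class = "gamma_model")
  dr <- NULL; dp <- NULL
  if (!is.null(obj$delta_refine))
    dr <- structure(list(W = as.matrix(obj$delta_refine$W),
                         b = as.numeric(obj$delta_refine$b),
                         target_kind = obj$delta_refine$target_kind),
                    class = "delta_model")
  if (!is.null(obj$delta_props))
    dp <- lapply(obj$delta_props, function(l)
      structure(list(W = as.matrix(l$W), b = as.numeric(l$b),
                     target_kind = l$target_kind), class = "delta_model"))
  model_stack(gm, flavor = obj$flavor, delta_refine = dr, delta_props = dp)
}

#' Save / load a training set
#'
#' JSON archive of the feature/target arrays, energies, forces, reference
#' geometry, method and provenance (temperature, seed).
#'
#' @param ts a `training_set`.
#' @param path file path.
#' @return `save_training_set`: `path` invisibly; `load_training_set`: a
#'   `training_set` (without the in-memory sampler provenance needed by
#'   [grow_training_set()]).
#' @export
save_training_set <- function(ts, path) {
  obj <- list(
    format = "rdmlearn-training-set", version = ARCHIVE_VERSION,
    method = ts$method[c("functional", "basis", "scf_convergence")],
    M = ts$M, ref = geometry_to_list(ts$ref),
    X = ts$X, Y = ts$Y, energies = ts$energies,
    forces = lapply(ts$forces, identity),
    positions = lapply(ts$geometries, function(g) g$positions),
    temperature = ts$provenance$temperature %||% NA,
    seed = ts$provenance$seed %||% NA)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_training_set
#' @export
load_training_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "rdmlearn-training-set"))
    stop("not a training-set archive: ", path)
  ref <- geometry_from_list(obj$ref)
  method <- method_spec(obj$method$functional, obj$method$basis,
                        obj$method$scf_convergence)
  forces <- obj$forces
  if (is.array(forces) && length(dim(forces)) == 3) {
    forces <- lapply(seq_len(dim(forces)[1]), function(i) forces[i, , ])
  }
  geoms <- NULL
  if (!is.null(obj$positions)) {
    pl <- obj$positions
    if (is.array(pl) && length(dim(pl)) == 3)
      pl <- lapply(seq_len(dim(pl)[1]), function(i) pl[i, , ])
    geoms <- lapply(pl, function(p) with_positions(ref, p))
  }
  structure(list(X = as.matrix(obj$X), Y = as.matrix(obj$Y),
                 energies = as.numeric(obj$energies), forces = forces,
                 transforms = NULL, geometries = geoms,
                 ref = ref, method = method, M = as.integer(obj$M),
                 provenance = list(temperature = obj$temperature,
                                   seed = obj$seed)),
            class = "training_set")
}
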