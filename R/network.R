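#' Four-region speech repetition network
#'
#' Constructs the fixed architecture used throughout the package: left primary
#' auditory cortex (A1), posterior superior temporal sulcus (pSTS), pars
#' opercularis (pOp, dorsal or ventral subdivision) and primary motor cortex
#' (M1, face or tongue-and-larynx subdivision). All 16 ordered region pairs
#' are connected except A1 -> M1, giving 15 connections of which 4 are
#' inhibitory self-connections. Driving input enters A1 only.
#'
#' The switchable set -- the connections eligible for pruning during model
#' space search -- defaults to the 8 extrinsic connections excluding the three
#' afferents to A1 (pSTS->A1, pOp->A1, M1->A1) and all self-connections, so the
#' model space has 2^8 = 256 members.
#'
#' @param pOp Which pars opercularis subdivision labels the third region,
#'   `"dpOp"` or `"vpOp"`.
#' @param M1 Which motor subdivision labels the fourth region, `"M1f"` or
#'   `"M1tl"`.
#' @param switchable Character vector of connection names (`"source->target"`)
#'   eligible for pruning, or `NULL` for the default 8-connection set.
#'
#' @return An object of class `network_spec`: region labels, the 4x4 logical
#'   `connection_mask` (rows = target, columns = source), the input region
#'   index, and the `switchable_mask`.
#' @export
#' @examples
#' spec <- network_spec()
#' sum(spec$connection_mask) # 15 connections
network_spec <- function(pOp = c("dpOp", "vpOp"), M1 = c("M1f", "M1tl"),
                         switchable = NULL) {
  pOp <- match.arg(pOp)
  M1 <- match.arg(M1)
  labels <- c("A1", "pSTS", "pOp", "M1")
  region_names <- c("A1", "pSTS", pOp, M1)

  mask <- matrix(TRUE, 4, 4, dimnames = list(target = labels, source = labels))
  mask["M1", "A1"] <- FALSE  # the one absent pair: A1 -> M1

  default_switchable <- c(
    "A1->pSTS", "A1->pOp", "pSTS->pOp", "pSTS->M1",
    "pOp->pSTS", "pOp->M1", "M1->pSTS", "M1->pOp"
  )
  switchable <- switchable %||% default_switchable
  smask <- matrix(FALSE, 4, 4, dimnames = dimnames(mask))
  for (nm in switchable) {
    st <- parse_connection(nm, labels)
    if (st[1] == st[2]) {
      stop("self-connections are never switchable: ", nm, call. = FALSE)
    }
    if (!mask[st[2], st[1]]) {
      stop("connection not present in the architecture: ", nm, call. = FALSE)
    }
    smask[st[2], st[1]] <- TRUE
  }

  structure(
    list(
      region_labels = labels,
      region_names = region_names,
      connection_mask = mask,
      input_region = 1L,
      switchable_mask = smask
    ),
    class = "network_spec"
  )
}

parse_connection <- function(name, labels) {
  parts <- strsplit(name, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% labels)) {
    stop("malformed connection name: ", name, call. = FALSE)
  }
  parts
}

connection_name <- function(source, target) paste0(source, "->", target)

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> regions:", paste(x$region_names, collapse = ", "), "\n")
  cat("  connections:", sum(x$connection_mask),
      "(", sum(diag(x$connection_mask)), "self )\n")
  cat("  switchable:", sum(x$switchable_mask),
      "-> model space of", 2^sum(x$switchable_mask), "models\n")
  invisible(x)
}

#' Tidy the connection table of a network
#'
#' @param x A [network_spec()].
#' @param ... Unused.
#' @return A tibble with one row per connection: `source`, `target`,
#'   `connection`, `self`, `switchable`.
#' @export
tidy.network_spec <- function(x, ...) {
  idx <- which(x$connection_mask, arr.ind = TRUE)
  tibble::tibble(
    source = x$region_labels[idx[, 2]],
    target = x$region_labels[idx[, 1]],
    connection = connection_name(x$region_labels[idx[, 2]],
                                 x$region_labels[idx[, 1]]),
    self = idx[, 1] == idx[, 2],
    switchable = x$switchable_mask[idx]
  ) |> dplyr::arrange(.data$target, .data$source)
}

# Canonical parameter ordering: extrinsic rates by (target, source) row-major
# over masked non-self pairs, then 4 self log-scalings, then the input gain,
# then 4 decay and 4 transit log-scalings.
param_names <- function(spec) {
  labels <- spec$region_labels
  ext <- character(0)
  for (t in 1:4) {
    for (s in 1:4) {
      if (t != s && spec$connection_mask[t, s]) {
        ext <- c(ext, connection_name(labels[s], labels[t]))
      }
    }
  }
  c(ext,
    paste0("self_", labels),
    "input_gain",
    paste0("decay_", labels),
    paste0("transit_", labels))
}

extrinsic_names <- function(spec) {
  nm <- param_names(spec)
  nm[seq_len(sum(spec$connection_mask) - 4L)]
}

connectivity_names <- function(spec) {
  c(extrinsic_names(spec), paste0("self_", spec$region_labels), "input_gain")
}

n_params <- function(spec) sum(spec$connection_mask) - 4L + 4L + 1L + 8L

#' DCM parameter vector
#'
#' Bundles one subject-level model's parameters: extrinsic rate constants (Hz)
#' for the 11 between-region connections, 4 dimensionless self-connection
#' log-scalings (the effective self-connection is `-0.5 * exp(scaling)` Hz, so
#' a positive estimate means greater self-inhibition), the driving input gain
#' into A1, and per-region hemodynamic decay/transit log-scalings.
#'
#' @param spec A [network_spec()].
#' @param extrinsic Named numeric vector of rates in Hz, names
#'   `"source->target"`; connections not named default to 0. Naming a pair
#'   absent from the architecture (A1->M1 or a self pair) is an error.
#' @param self_scaling Numeric length 4 (A1, pSTS, pOp, M1) or named subset.
#' @param input_gain Scalar, Hz per unit input.
#' @param decay_scaling,transit_scaling Numeric length 4 or named subset
#'   (names = region labels); log-scalings of kappa0 = 0.64 1/s and
#'   tau0 = 2.0 s.
#' @return An object of class `dcm_params`.
#' @export
dcm_params <- function(spec, extrinsic = numeric(0), self_scaling = 0,
                       input_gain = 0, decay_scaling = 0, transit_scaling = 0) {
  stopifnot(inherits(spec, "network_spec"))
  ext_names <- extrinsic_names(spec)
  ext <- setNames(numeric(length(ext_names)), ext_names)
  if (length(extrinsic)) {
    bad <- setdiff(names(extrinsic), ext_names)
    if (length(bad)) {
      stop("parameter supplied for a connection absent from the architecture: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    ext[names(extrinsic)] <- extrinsic
  }
  expand4 <- function(x, prefix) {
    labels <- spec$region_labels
    out <- setNames(numeric(4), labels)
    if (!is.null(names(x)) && length(names(x))) {
      stopifnot(all(names(x) %in% labels))
      out[names(x)] <- x
    } else {
      out[] <- rep_len(x, 4)
    }
    out
  }
  structure(
    list(
      extrinsic = ext,
      self_scaling = expand4(self_scaling),
      input_gain = unname(input_gain),
      decay_scaling = expand4(decay_scaling),
      transit_scaling = expand4(transit_scaling),
      spec = spec
    ),
    class = "dcm_params"
  )
}

#' Flatten / rebuild a parameter vector
#'
#' The flattening is the canonical ordering used by the estimator: extrinsic
#' rates by (target, source) row-major, then self-scalings, input gain and the
#' 8 hemodynamic scalings. `flatten_params()` and `unflatten_params()` are
#' exact inverses.
#'
#' @param params A [dcm_params()] object.
#' @param theta Named numeric vector in canonical order.
#' @param spec A [network_spec()].
#' @return A named numeric vector, or a `dcm_params` object.
#' @export
flatten_params <- function(params) {
  stopifnot(inherits(params, "dcm_params"))
  spec <- params$spec
  out <- c(params$extrinsic,
           setNames(params$self_scaling, paste0("self_", spec$region_labels)),
           input_gain = params$input_gain,
           setNames(params$decay_scaling, paste0("decay_", spec$region_labels)),
           setNames(params$transit_scaling, paste0("transit_", spec$region_labels)))
  stopifnot(identical(names(out), param_names(spec)))
  out
}

#' @rdname flatten_params
#' @export
unflatten_params <- function(theta, spec) {
  nm <- param_names(spec)
  stopifnot(length(theta) == length(nm))
  if (is.null(names(theta))) names(theta) <- nm
  labels <- spec$region_labels
  n_ext <- length(nm) - 13L
  structure(
    list(
      extrinsic = theta[seq_len(n_ext)],
      self_scaling = setNames(unname(theta[n_ext + 1:4]), labels),
      input_gain = unname(theta[[n_ext + 5L]]),
      decay_scaling = setNames(unname(theta[n_ext + 5L + 1:4]), labels),
      transit_scaling = setNames(unname(theta[n_ext + 9L + 1:4]), labels),
      spec = spec
    ),
    class = "dcm_params"
  )
}

#' Effective connectivity matrix
#'
#' Assembles the 4x4 rate matrix A (Hz) of the neural model dx/dt = Ax + Cu.
#' Diagonal entries are `-0.5 * exp(self_scaling)` so the network is
#' self-inhibiting at the prior mean (-0.5 Hz) and a positive self estimate
#' means stronger self-inhibition; off-diagonal entry (target, source) is the
#' extrinsic rate when the connection exists and 0 otherwise (A1 -> M1 is
#' structurally absent).
#'
#' @param params A [dcm_params()] object.
#' @return A 4x4 numeric matrix, rows = target, columns = source.
#' @export
#' @examples
#' spec <- network_spec()
#' build_effective_A(dcm_params(spec)) # diag(-0.5, 4)
build_effective_A <- function(params) {
  stopifnot(inherits(params, "dcm_params"))
  spec <- params$spec
  labels <- spec$region_labels
  A <- matrix(0, 4, 4, dimnames = list(target = labels, source = labels))
  diag(A) <- -0.5 * exp(params$self_scaling)
  for (nm in names(params$extrinsic)) {
    st <- parse_connection(nm, labels)
    A[st[2], st[1]] <- params$extrinsic[[nm]]
  }
  A
}
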