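#' @useDynLib nodulecascade, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif median
NULL

# ---- parameters -------------------------------------------------------------

# A parameter is a mutable cell: $value, accumulated $grad, Adam state $m/$v.
nc_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- NULL
  p$v <- NULL
  p
}

new_module <- function(type, cfg = list()) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$cfg <- cfg
  m$params <- list()     # named list of nc_param
  m$children <- list()   # named list of submodules
  m$state <- list()      # non-trained state (e.g. BN running stats)
  class(m) <- c(paste0("nc_", type), "nc_module")
  m
}

# Truncated normal initialiser (resample beyond 2 sd); deterministic under seed.
trunc_normal <- function(n, sd) {
  x <- rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

# Recursively collect parameters with path-qualified names.
module_params <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) out[[paste0(prefix, nm)]] <- m$params[[nm]]
  for (nm in names(m$children))
    out <- c(out, module_params(m$children[[nm]], paste0(prefix, nm, ".")))
  out
}

module_state <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$state)) out[[paste0(prefix, nm)]] <- m$state[[nm]]
  for (nm in names(m$children))
    out <- c(out, module_state(m$children[[nm]], paste0(prefix, nm, ".")))
  out
}

set_module_state <- function(m, st, prefix = "") {
  for (nm in names(m$state)) {
    key <- paste0(prefix, nm)
    if (!is.null(st[[key]])) m$state[[nm]] <- st[[key]]
  }
  for (nm in names(m$children))
    set_module_state(m$children[[nm]], st, paste0(prefix, nm, "."))
  invisible(m)
}

#' Number of trainable parameters in a network
#'
#' @param net a network or module built by this package.
#' @return integer count of scalar trainable parameters.
#' @export
count_params <- function(net) {
  ps <- module_params(net)
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}

# Flat named list of parameter values (copies).
param_values <- function(net) lapply(module_params(net), function(p) p$value)

# Load values produced by param_values() back into a network (by name).
set_param_values <- function(net, values, strict = TRUE) {
  ps <- module_params(net)
  for (nm in names(values)) {
    if (is.null(ps[[nm]])) {
      if (strict) stop("unknown parameter in state: ", nm)
      next
    }
    if (!identical(dim(ps[[nm]]$value), dim(values[[nm]])) ||
        length(ps[[nm]]$value) != length(values[[nm]]))
      stop("parameter shape mismatch for ", nm)
    ps[[nm]]$value <- values[[nm]]
  }
  invisible(net)
}

zero_grads <- function(net) {
  params <- if (inherits(net, "nc_module")) module_params(net) else net
  for (p in params) p$grad <- NULL
  invisible(net)
}

# ---- layer inspection -------------------------------------------------------

#' Flat table of the layers in a network
#'
#' Walks the module tree and returns one row per layer with its structural
#' configuration, for architecture assertions (e.g. that a backbone contains
#' no pooling other than the mask/area downsampling, or that particular
#' convolutions are dilated).
#'
#' @param net a network or module.
#' @return a data.frame with columns `path`, `type`, `kernel`, `stride`,
#'   `dilation`, `padding`, `groups`, `in_ch`, `out_ch` (NA where a field does
#'   not apply).
#' @export
network_layers <- function(net) {
  rows <- list()
  walk <- function(m, path) {
    g <- function(x) if (is.null(m$cfg[[x]])) NA else m$cfg[[x]]
    rows[[length(rows) + 1L]] <<- data.frame(
      path = path, type = m$type,
      kernel = g("kernel"), stride = g("stride"), dilation = g("dilation"),
      padding = g("padding"), groups = g("groups"),
      in_ch = g("in_ch"), out_ch = g("out_ch"),
      stringsAsFactors = FALSE)
    for (nm in names(m$children)) walk(m$children[[nm]], paste0(path, "/", nm))
  }
  walk(net, net$type)
  do.call(rbind, rows)
}

# ---- optimiser --------------------------------------------------------------

adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e
}

# `net` may be a module or a pre-collected module_params() list; training
# loops pass the list to avoid re-walking the module tree every step.
adam_step <- function(net, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1t <- 1 - beta1^opt$t
  b2t <- 1 - beta2^opt$t
  params <- if (inherits(net, "nc_module")) module_params(net) else net
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$m)) {
      p$m <- p$grad * 0
      p$v <- p$grad * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    p$value <- p$value - lr * (p$m / b1t) / (sqrt(p$v / b2t) + eps)
  }
  invisible(net)
}

# ---- checkpoints ------------------------------------------------------------

#' Save a network checkpoint
#'
#' Stores the trainable parameters, the batch-norm running statistics and the
#' full build specification. [load_checkpoint()] refuses to restore into a
#' build whose specification disagrees with the stored one.
#'
#' @param net the network.
#' @param spec the specification the network was built from
#'   ([backbone_spec()] or [classnet_spec()], possibly with extra fields).
#' @param path file path to write.
#' @param meta optional list of extra metadata (training log, epoch, ...).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, spec, path, meta = list()) {
  ck <- list(spec = spec,
             params = param_values(net),
             state = module_state(net),
             meta = meta)
  saveRDS(ck, path)
  invisible(path)
}

#' Read a checkpoint file
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @param expect_spec if given, the build specification the caller is about to
#'   use; an error is raised when it disagrees with the stored one.
#' @return the checkpoint list (`spec`, `params`, `state`, `meta`).
#' @export
load_checkpoint <- function(path, expect_spec = NULL) {
  ck <- readRDS(path)
  if (!is.null(expect_spec) && !isTRUE(all.equal(ck$spec, expect_spec)))
    stop("checkpoint spec disagrees with the requested build")
  ck
}

restore_network <- function(net, ck) {
  set_param_values(net, ck$params)
  set_module_state(net, ck$state)
  invisible(net)
}
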