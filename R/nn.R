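# ---------------------------------------------------------------------------
# Network container: parameters live in a flat named list `net$par`; layers
# store only hyperparameters.  During a training step the parameter arrays are
# wrapped as autograd leaves, so the same forward code runs taped or plain.
# ---------------------------------------------------------------------------

new_net <- function(config = list()) {
  net <- new.env(parent = emptyenv())
  net$par <- list()
  net$layers <- list()
  net$config <- config
  class(net) <- "nodule_net"
  net
}

#' @export
print.nodule_net <- function(x, ...) {
  cat("<nodule_net> ", length(x$layers), " layers, ",
      format(n_parameters(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters
#' @param net A `nodule_net`.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$par, length, numeric(1)))
}

# Register a conv layer (optionally BN and/or ReLU). He-normal init; draws
# come from the current RNG stream so a seeded build is reproducible.
add_conv <- function(net, name, cin, cout, kh = 3L, kw = kh, stride = 1L,
                     dilation = 1L, bias = TRUE, bn = FALSE, act = c("none", "relu")) {
  act <- match.arg(act)
  if (bn) bias <- FALSE
  fan_in <- kh * kw * cin
  net$par[[paste0(name, ".w")]] <-
    array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
          c(kh, kw, cin, cout))
  if (bias) net$par[[paste0(name, ".b")]] <- numeric(cout)
  if (bn) {
    net$par[[paste0(name, ".g")]] <- rep(1, cout)
    net$par[[paste0(name, ".bb")]] <- rep(0, cout)
  }
  net$layers[[name]] <- list(kind = "conv", cin = cin, cout = cout,
                             kh = kh, kw = kw, stride = stride,
                             dilation = dilation, bias = bias, bn = bn, act = act)
  invisible(net)
}

# Apply a registered conv layer; `p` is net$par or its ag-wrapped counterpart.
conv_apply <- function(net, name, x, p) {
  L <- net$layers[[name]]
  if (is.null(L)) stop("unknown layer: ", name)
  y <- ag_conv2d(x, p[[paste0(name, ".w")]],
                 if (L$bias) p[[paste0(name, ".b")]] else NULL,
                 stride = L$stride, pad = "same", dilation = L$dilation)
  if (L$bn) y <- ag_bn(y, p[[paste0(name, ".g")]], p[[paste0(name, ".bb")]])
  if (L$act == "relu") y <- ag_relu(y)
  y
}

# wrap all parameters as autograd leaves for one training step
wrap_params <- function(net) {
  lapply(net$par, function(a) ag(a, requires_grad = TRUE))
}

collect_grads <- function(pnodes) {
  lapply(pnodes, function(n) {
    if (is.null(n$grad)) {
      if (is.null(dim(n$value))) numeric(length(n$value)) else array(0, dim(n$value))
    } else n$grad
  })
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(par) {
  list(m = lapply(par, function(a) a * 0),
       v = lapply(par, function(a) a * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(par)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    par[[k]] <- par[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(par = par, state = state)
}
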