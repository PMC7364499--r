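#' Initialize LSTM parameters
#'
#' Weight matrices follow the gate equations: `W_x*` maps the token input,
#' `W_h*` the previous hidden state, for the input (`i`), forget (`f`),
#' output (`o`) and candidate (`g`) gates. Weights start uniform in
#' `[-scale, scale]`, biases at zero.
#'
#' @param input_dim dimension of the token representation.
#' @param hidden hidden state size per direction (default 200).
#' @param scale uniform init half-width (default 0.08).
#' @param seed integer seed.
#' @return object of class `lstm_params` (a named list of matrices and
#'   bias vectors).
#' @export
lstm_params <- function(input_dim, hidden = 200L, scale = 0.08, seed = 1L) {
  input_dim <- stopifnot_scalar_int(input_dim, "input_dim")
  hidden <- stopifnot_scalar_int(hidden, "hidden")
  with_seed(derive_seed(seed, "init"), {
    mat <- function(nr, nc) matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
    p <- list()
    for (gate in c("i", "f", "o", "g")) {
      p[[paste0("W_x", gate)]] <- mat(input_dim, hidden)
      p[[paste0("W_h", gate)]] <- mat(hidden, hidden)
      p[[paste0("b_", gate)]] <- numeric(hidden)
    }
    structure(c(p, list(input_dim = input_dim, hidden = hidden)),
              class = "lstm_params")
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# one LSTM step; h_drop is a variational dropout multiplier applied to
# h_prev where it enters a recurrent weight product (1s = no dropout)
lstm_step <- function(x, h_prev, c_prev, params, variant, h_drop = NULL) {
  hp <- if (is.null(h_drop)) h_prev else h_prev * h_drop
  a_i <- drop(x %*% params$W_xi) + drop(hp %*% params$W_hi) + params$b_i
  a_f <- drop(x %*% params$W_xf) + drop(hp %*% params$W_hf) + params$b_f
  a_o <- drop(x %*% params$W_xo) + drop(hp %*% params$W_ho) + params$b_o
  i <- sigmoid(a_i); f <- sigmoid(a_f); o <- sigmoid(a_o)
  if (variant == "literal") {
    ihp <- i * hp
    g <- tanh(drop(x %*% params$W_xg) + drop(ihp %*% params$W_hg) + params$b_g)
    c_t <- f * c_prev + i * g
    h_t <- (1 - f) * h_prev + f * g
  } else {
    ihp <- hp
    g <- tanh(drop(x %*% params$W_xg) + drop(hp %*% params$W_hg) + params$b_g)
    c_t <- f * c_prev + i * g
    h_t <- o * tanh(c_t)
  }
  list(h = h_t, c = c_t,
       cache = list(x = x, h_prev = h_prev, hp = hp, c_prev = c_prev,
                    i = i, f = f, o = o, g = g, ihp = ihp, c_t = c_t))
}

#' One step of the LSTM unit
#'
#' Two gate wirings are provided. In the `"literal"` wiring the candidate
#' gate reads `i * h_prev` and the new hidden state is the convex mix
#' `(1-f)*h_prev + f*g` (the output gate and cell state are computed but do
#' not feed `h`); `"standard"` is the textbook cell with `h = o * tanh(c)`.
#'
#' @param x input vector for the current step.
#' @param h_prev,c_prev previous hidden and cell state vectors.
#' @param params an [lstm_params()] object.
#' @param variant `"literal"` (default) or `"standard"`.
#' @return list with vectors `h` and `c`.
#' @examples
#' p <- lstm_params(2, 3)
#' st <- lstm_cell(c(0.1, -0.2), numeric(3), numeric(3), p)
#' @export
lstm_cell <- function(x, h_prev, c_prev, params,
                      variant = c("literal", "standard")) {
  variant <- match.arg(variant)
  if (length(x) != params$input_dim || length(h_prev) != params$hidden ||
      length(c_prev) != params$hidden)
    stop("lstm_cell: shape mismatch with params")
  st <- lstm_step(x, h_prev, c_prev, params, variant)
  list(h = st$h, c = st$c)
}

# forward pass over a full (unpadded) sequence; returns H (n x hidden)
# and the per-step caches needed for backpropagation through time
lstm_forward <- function(X, params, variant, h_drop = NULL) {
  n <- nrow(X); H <- params$hidden
  h <- numeric(H); c <- numeric(H)
  out <- matrix(0, n, H)
  caches <- vector("list", n)
  for (t in seq_len(n)) {
    st <- lstm_step(X[t, ], h, c, params, variant, h_drop)
    h <- st$h; c <- st$c
    out[t, ] <- h
    caches[[t]] <- st$cache
  }
  list(H = out, caches = caches)
}

zero_like_lstm <- function(params) {
  g <- list()
  for (nm in c("W_xi", "W_hi", "W_xf", "W_hf", "W_xo", "W_ho", "W_xg", "W_hg"))
    g[[nm]] <- params[[nm]] * 0
  for (nm in c("b_i", "b_f", "b_o", "b_g")) g[[nm]] <- params[[nm]] * 0
  g
}

# backpropagation through time; dH is n x hidden (dLoss/dh_t).
# Returns parameter gradients and dX.
lstm_backward <- function(dH, fwd, params, variant, h_drop = NULL) {
  caches <- fwd$caches
  n <- nrow(dH); H <- params$hidden
  g <- zero_like_lstm(params)
  dX <- matrix(0, n, params$input_dim)
  dh_next <- numeric(H); dc_next <- numeric(H)
  m <- if (is.null(h_drop)) rep(1, H) else h_drop
  for (t in rev(seq_len(n))) {
    cc <- caches[[t]]
    dh <- dH[t, ] + dh_next
    dc <- dc_next
    if (variant == "literal") {
      dg <- dh * cc$f + dc * cc$i
      df <- dh * (cc$g - cc$h_prev) + dc * cc$c_prev
      di <- dc * cc$g
      do_ <- numeric(H)                       # o does not feed h_t here
      dh_prev <- dh * (1 - cc$f)
      dc_prev <- dc * cc$f
      da_g <- dg * (1 - cc$g^2)
      d_ihp <- drop(da_g %*% t(params$W_hg))
      di <- di + d_ihp * cc$hp
      dhp <- d_ihp * cc$i
    } else {
      tc <- tanh(cc$c_t)
      do_ <- dh * tc
      dc <- dc + dh * cc$o * (1 - tc^2)
      df <- dc * cc$c_prev
      di <- dc * cc$g
      dg <- dc * cc$i
      dh_prev <- numeric(H)
      dc_prev <- dc * cc$f
      da_g <- dg * (1 - cc$g^2)
      dhp <- drop(da_g %*% t(params$W_hg))
    }
    da_i <- di * cc$i * (1 - cc$i)
    da_f <- df * cc$f * (1 - cc$f)
    da_o <- do_ * cc$o * (1 - cc$o)
    dhp <- dhp + drop(da_i %*% t(params$W_hi)) +
                 drop(da_f %*% t(params$W_hf)) +
                 drop(da_o %*% t(params$W_ho))
    dh_prev <- dh_prev + dhp * m
    dx <- drop(da_i %*% t(params$W_xi)) + drop(da_f %*% t(params$W_xf)) +
          drop(da_o %*% t(params$W_xo)) + drop(da_g %*% t(params$W_xg))
    g$W_xi <- g$W_xi + outer(cc$x, da_i)
    g$W_xf <- g$W_xf + outer(cc$x, da_f)
    g$W_xo <- g$W_xo + outer(cc$x, da_o)
    g$W_xg <- g$W_xg + outer(cc$x, da_g)
    g$W_hi <- g$W_hi + outer(cc$hp, da_i)
    g$W_hf <- g$W_hf + outer(cc$hp, da_f)
    g$W_ho <- g$W_ho + outer(cc$hp, da_o)
    g$W_hg <- g$W_hg + outer(cc$ihp, da_g)
    g$b_i <- g$b_i + da_i; g$b_f <- g$b_f + da_f
    g$b_o <- g$b_o + da_o; g$b_g <- g$b_g + da_g
    dX[t, ] <- dx
    dh_next <- dh_prev; dc_next <- dc_prev
  }
  list(grads = g, dX = dX)
}

#' Bidirectional LSTM encoding of an embedded sequence
#'
#' Concatenates the forward hidden state with the backward hidden state of
#' each position: `h_i = [fwd_i ; bwd_i]`, with zero initial states. The
#' backward pass runs over the reversed valid region only; padded
#' positions (trailing `FALSE` entries of `mask`) carry zero vectors and
#' never influence valid outputs.
#'
#' @param embedded numeric matrix `n x input_dim`.
#' @param params_fwd,params_bwd [lstm_params()] for the two directions.
#' @param mask logical vector of valid positions (right padding only);
#'   `NULL` means all valid.
#' @param variant gate wiring, see [lstm_cell()].
#' @return object of class `encoded_sequence`: list with `H`
#'   (`n x 2*hidden`) and `mask`.
#' @export
encode_bilstm <- function(embedded, params_fwd, params_bwd, mask = NULL,
                          variant = c("literal", "standard")) {
  variant <- match.arg(variant)
  n <- nrow(embedded)
  if (is.null(n) || n == 0L) stop("cannot encode an empty sequence")
  mask <- mask %||% rep(TRUE, n)
  nv <- sum(mask)
  if (nv == 0L) stop("mask leaves no valid positions")
  if (!all(mask[seq_len(nv)]))
    stop("mask must be right padding: valid rows first")
  Xv <- embedded[seq_len(nv), , drop = FALSE]
  f <- lstm_forward(Xv, params_fwd, variant)
  b <- lstm_forward(Xv[rev(seq_len(nv)), , drop = FALSE], params_bwd, variant)
  Hb <- b$H[rev(seq_len(nv)), , drop = FALSE]
  out <- matrix(0, n, 2L * params_fwd$hidden)
  out[seq_len(nv), ] <- cbind(f$H, Hb)
  structure(list(H = out, mask = mask), class = "encoded_sequence")
}
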