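#' State activation map
#'
#' A state's posterior mean vector over regions, in the z-units of the
#' standardized data: positive entries mark regions whose signal sits above
#' their subject-wise temporal mean while the state is occupied (increased
#' activation), negative entries below it.
#'
#' @param model a `vbhmm`.
#' @param state state index in `1..K`.
#' @return named length-N numeric vector.
#' @export
state_activation_map <- function(model, state) {
  stopifnot(inherits(model, "vbhmm"))
  state <- assert_scalar_count(state, "state")
  if (state > model$n_states) {
    abort(sprintf("state %d out of range 1..%d", state, model$n_states))
  }
  setNames(model$state_means[state, ], model$region_labels)
}

#' State functional-connectivity matrix
#'
#' Converts a state's posterior covariance to a correlation matrix
#' (`D^{-1/2} Sigma D^{-1/2}`): symmetric, unit diagonal, entries in
#' `[-1, 1]`.
#'
#' @inheritParams state_activation_map
#' @return N x N correlation matrix with region labels as dimnames.
#' @export
state_fc_matrix <- function(model, state) {
  stopifnot(inherits(model, "vbhmm"))
  state <- assert_scalar_count(state, "state")
  if (state > model$n_states) {
    abort(sprintf("state %d out of range 1..%d", state, model$n_states))
  }
  S <- model$state_covariances[[state]]
  if (any(diag(S) <= 0)) abort("state covariance is not positive definite")
  C <- cov2cor(S)
  dimnames(C) <- list(model$region_labels, model$region_labels)
  C
}

#' Network-block summary of a connectivity matrix
#'
#' Averages connectivity over all region pairs within and between networks:
#' entry (a, b) is the mean of `fc[i, j]` over pairs with region i in
#' network a, region j in network b and `i != j`; diagonal blocks therefore
#' use off-diagonal pairs only. Networks with fewer than two regions get a
#' missing within-network value; networks absent from the parcellation get
#' missing rows/columns.
#'
#' @param fc symmetric N x N connectivity matrix with region labels as
#'   column names.
#' @param networks region-to-network lookup (see [load_network_table()]).
#' @return 10 x 10 symmetric matrix over [network_tags].
#' @export
network_block_summary <- function(fc, networks) {
  fc <- as.matrix(fc)
  if (nrow(fc) != ncol(fc) || max(abs(fc - t(fc))) > 1e-8) {
    abort("`fc` must be a symmetric square matrix")
  }
  labels <- colnames(fc)
  if (is.null(labels)) abort("`fc` needs region labels as column names")
  idx <- match(labels, networks$region_label)
  if (anyNA(idx)) {
    abort(sprintf("unlabelled region(s): %s",
                  paste(labels[is.na(idx)], collapse = ", ")))
  }
  tag <- as.character(networks$network[idx])
  tags <- network_tags
  out <- matrix(NA_real_, length(tags), length(tags),
                dimnames = list(tags, tags))
  for (a in seq_along(tags)) for (b in a:length(tags)) {
    ia <- which(tag == tags[a]); ib <- which(tag == tags[b])
    if (!length(ia) || !length(ib)) next
    if (a == b) {
      if (length(ia) < 2) next
      block <- fc[ia, ia, drop = FALSE]
      val <- mean(block[upper.tri(block)])
    } else {
      val <- mean(fc[ia, ib, drop = FALSE])
    }
    out[a, b] <- out[b, a] <- val
  }
  out
}
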