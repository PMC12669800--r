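#' @title Task heads: occurrence, site, affinity
#' @description The three information-adaptive heads that interpret the
#'   shared encoder outputs: a dual-pathway gated cross-attention classifier
#'   for binding occurrence, cross- plus self-attention with gated fusion
#'   for residue-level site probabilities, and typed attention convolutions
#'   on the heterogeneous interface graph for affinity regression.
#' @name decoders
NULL

## standard multi-head scaled dot-product attention; inputs are the
## unprojected feature matrices, projections WQ/WK/WV and output WO applied
## inside, heads split along the feature dimension
mha_f <- function(Hq, Hk, Hv, WQ, WK, WV, WO, heads) {
  q <- ad_matmul(Hq, WQ)
  k <- ad_matmul(Hk, WK)
  v <- ad_matmul(Hv, WV)
  d <- ncol(q$value)
  stopifnot(d %% heads == 0L)
  hd <- d %/% heads
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * hd + 1L):(h * hd)
    qh <- ad_slice_cols(q, idx)
    kh <- ad_slice_cols(k, idx)
    vh <- ad_slice_cols(v, idx)
    att <- ad_softmax_rows(ad_smul(ad_matmul_t(qh, kh), 1 / sqrt(hd)))
    outs[[h]] <- ad_matmul(att, vh)
  }
  ad_matmul(ad_cbind(outs), WO)
}

## two-layer MLP helper: W2 (act(W1 x + b1)) + b2
mlp2_f <- function(x, W1, b1, W2, b2, slope) {
  nn_linear(ad_leaky_relu(nn_linear(x, W1, b1), slope), W2, b2)
}

## ---- occurrence head ----------------------------------------------------

#' Initialize binding-occurrence head parameters
#' @param config a [model_config()].
#' @return named list of matrices, prefixed \code{occ.}.
#' @export
init_occurrence_params <- function(config) {
  h1 <- config$h1; h3 <- config$h3; h4 <- config$h4
  h4h <- max(1L, h4 %/% 2L)
  p <- list(
    occ.Wp1 = glorot(h1, h4), occ.Wd1 = glorot(h3, h4),
    occ.WQp = glorot(h4, h4), occ.WKd = glorot(h4, h4),
    occ.WVd = glorot(h4, h4), occ.WOp = glorot(h4, h4),
    occ.WQd = glorot(h4, h4), occ.WKp = glorot(h4, h4),
    occ.WVp = glorot(h4, h4), occ.WOd = glorot(h4, h4),
    occ.lnp_g = matrix(1, 1, h4), occ.lnp_b = matrix(0, 1, h4),
    occ.lnd_g = matrix(1, 1, h4), occ.lnd_b = matrix(0, 1, h4),
    occ.Wgp = glorot(2L * h4, h4), occ.Wgd = glorot(2L * h4, h4),
    occ.Wpr = glorot(h4, h4), occ.Wdr = glorot(h4, h4),
    occ.Wpm1 = glorot(h4, h4), occ.bpm1 = matrix(0, 1, h4),
    occ.Wpm2 = glorot(h4, h4), occ.bpm2 = matrix(0, 1, h4),
    occ.Wdm1 = glorot(h4, h4), occ.bdm1 = matrix(0, 1, h4),
    occ.Wdm2 = glorot(h4, h4), occ.bdm2 = matrix(0, 1, h4),
    occ.Wc1 = glorot(4L * h4, 2L * h4), occ.bc1 = matrix(0, 1, 2L * h4),
    occ.ln1_g = matrix(1, 1, 2L * h4), occ.ln1_b = matrix(0, 1, 2L * h4),
    occ.Wc2 = glorot(2L * h4, h4), occ.bc2 = matrix(0, 1, h4),
    occ.ln2_g = matrix(1, 1, h4), occ.ln2_b = matrix(0, 1, h4),
    occ.Wc3 = glorot(h4, h4h), occ.bc3 = matrix(0, 1, h4h),
    occ.ln3_g = matrix(1, 1, h4h), occ.ln3_b = matrix(0, 1, h4h),
    occ.Wc4 = glorot(h4h, 1L), occ.bc4 = matrix(0, 1, 1))
  p
}

#' Occurrence head forward pass (tape form)
#' @keywords internal
predict_occurrence_f <- function(Hp, Hd, P, config, train = FALSE) {
  slope <- config$leaky_slope
  Hp0 <- ad_leaky_relu(ad_matmul(Hp, P$occ.Wp1), slope)
  Hd0 <- ad_leaky_relu(ad_matmul(Hd, P$occ.Wd1), slope)
  att_p <- mha_f(Hp0, Hd0, Hd0, P$occ.WQp, P$occ.WKd, P$occ.WVd,
                 P$occ.WOp, config$heads)
  Hp1 <- ad_layernorm(ad_add(Hp0, att_p), P$occ.lnp_g, P$occ.lnp_b)
  att_d <- mha_f(Hd0, Hp0, Hp0, P$occ.WQd, P$occ.WKp, P$occ.WVp,
                 P$occ.WOd, config$heads)
  Hd1 <- ad_layernorm(ad_add(Hd0, att_d), P$occ.lnd_g, P$occ.lnd_b)
  gp <- ad_sigmoid(ad_matmul(ad_cbind(list(Hp1, Hp0)), P$occ.Wgp))
  Hpf <- ad_add(ad_mul(gp, Hp1), ad_mul(ad_one_minus(gp), Hp0))
  gd <- ad_sigmoid(ad_matmul(ad_cbind(list(Hd1, Hd0)), P$occ.Wgd))
  Hdf <- ad_add(ad_mul(gd, Hd1), ad_mul(ad_one_minus(gd), Hd0))
  zp <- ad_add(ad_colmean(Hpf), ad_colmax(Hpf))
  zd <- ad_add(ad_colmean(Hdf), ad_colmax(Hdf))
  zp1 <- ad_add(mlp2_f(zp, P$occ.Wpm1, P$occ.bpm1, P$occ.Wpm2, P$occ.bpm2,
                       slope),
                ad_matmul(zp, P$occ.Wpr))
  zd1 <- ad_add(mlp2_f(zd, P$occ.Wdm1, P$occ.bdm1, P$occ.Wdm2, P$occ.bdm2,
                       slope),
                ad_matmul(zd, P$occ.Wdr))
  z <- ad_cbind(list(zp1, zd1, ad_mul(zp1, zd1), ad_sub(zp1, zd1)))
  h <- ad_dropout(ad_layernorm(
    ad_leaky_relu(nn_linear(z, P$occ.Wc1, P$occ.bc1), slope),
    P$occ.ln1_g, P$occ.ln1_b), config$dropout, train)
  h <- ad_dropout(ad_layernorm(
    ad_leaky_relu(nn_linear(h, P$occ.Wc2, P$occ.bc2), slope),
    P$occ.ln2_g, P$occ.ln2_b), config$dropout, train)
  h <- ad_dropout(ad_layernorm(
    ad_leaky_relu(nn_linear(h, P$occ.Wc3, P$occ.bc3), slope),
    P$occ.ln3_g, P$occ.ln3_b), config$dropout, train)
  list(prob = ad_sigmoid(nn_linear(h, P$occ.Wc4, P$occ.bc4)), z = z)
}

#' Predict binding occurrence
#'
#' @param Hp N_p x h1 protein residue embeddings ([encode_protein()]).
#' @param Hd N_d x h3 drug atom embeddings ([encode_drug()]).
#' @param params occurrence parameters ([init_occurrence_params()]).
#' @param config a [model_config()].
#' @return list with \code{probability} (scalar in \[0,1\]) and \code{z}
#'   (the 4*h4 fused interaction vector).
#' @export
predict_occurrence <- function(Hp, Hd, params, config = model_config()) {
  if (!nrow(Hp) || !nrow(Hd)) stop("protein and drug encodings must be nonempty")
  ad_reset()
  P <- ad_wrap_params(params)
  out <- predict_occurrence_f(ad_leaf(Hp, track = FALSE),
                              ad_leaf(Hd, track = FALSE), P, config)
  res <- list(probability = as.numeric(out$prob$value),
              z = as.numeric(out$z$value))
  ad_reset()
  res
}

## ---- site head ----------------------------------------------------------

#' Initialize binding-site head parameters
#' @param config a [model_config()].
#' @return named list of matrices, prefixed \code{site.}.
#' @export
init_site_params <- function(config) {
  h1 <- config$h1; h3 <- config$h3; h5 <- config$h5
  list(
    site.Wp2 = glorot(h1, h5), site.Wd2 = glorot(h3, h5),
    site.WQp = glorot(h5, h5), site.WKd = glorot(h5, h5),
    site.WVd = glorot(h5, h5), site.WOc = glorot(h5, h5),
    site.WQ = glorot(h5, h5), site.WK = glorot(h5, h5),
    site.WV = glorot(h5, h5), site.WOs = glorot(h5, h5),
    site.Wg = glorot(2L * h5, h5),
    site.Wr = glorot(h5, 1L),
    site.Wm1 = glorot(h5, 2L * h5), site.bm1 = matrix(0, 1, 2L * h5),
    site.Wm2 = glorot(2L * h5, 1L), site.bm2 = matrix(0, 1, 1))
}

#' Site head forward pass (tape form)
#' @keywords internal
predict_sites_f <- function(Hp, Hd, P, config, train = FALSE) {
  slope <- config$leaky_slope
  Hp0 <- ad_leaky_relu(ad_matmul(Hp, P$site.Wp2), slope)
  Hd0 <- ad_leaky_relu(ad_matmul(Hd, P$site.Wd2), slope)
  Hc <- ad_add(Hp0, mha_f(Hp0, Hd0, Hd0, P$site.WQp, P$site.WKd,
                          P$site.WVd, P$site.WOc, config$heads))
  Hs <- mha_f(Hc, Hc, Hc, P$site.WQ, P$site.WK, P$site.WV, P$site.WOs,
              config$heads)
  g <- ad_sigmoid(ad_matmul(ad_cbind(list(Hc, Hs)), P$site.Wg))
  Z <- ad_add(ad_mul(g, Hc), ad_mul(ad_one_minus(g), Hs))
  logits <- ad_add(ad_matmul(Z, P$site.Wr),
                   mlp2_f(Z, P$site.Wm1, P$site.bm1, P$site.Wm2, P$site.bm2,
                          slope))
  ad_sigmoid(logits)
}

#' Predict per-residue binding-site probabilities
#'
#' @inheritParams predict_occurrence
#' @param params site parameters ([init_site_params()]).
#' @return numeric vector of length N_p, entries in \[0,1\].
#' @export
predict_sites <- function(Hp, Hd, params, config = model_config()) {
  if (!nrow(Hp) || !nrow(Hd)) stop("protein and drug encodings must be nonempty")
  ad_reset()
  P <- ad_wrap_params(params)
  out <- predict_sites_f(ad_leaf(Hp, track = FALSE),
                         ad_leaf(Hd, track = FALSE), P, config)
  v <- as.numeric(out$value)
  ad_reset()
  v
}

## ---- affinity head ------------------------------------------------------

#' Initialize binding-affinity head parameters
#'
#' The heterogeneous convolution carries per-layer weights (unlike the
#' shared-weight protein encoder). A value projection from the concatenated
#' \[neighbour || edge\] vector to h6 makes the printed update dimensionally
#' consistent.
#'
#' @param config a [model_config()].
#' @return named list of matrices, prefixed \code{aff.}.
#' @export
init_affinity_params <- function(config) {
  h1 <- config$h1; h3 <- config$h3; h6 <- config$h6
  p <- list(
    aff.Wpin = glorot(h1, h6), aff.bpin = matrix(0, 1, h6),
    aff.Wdin = glorot(h3, h6), aff.bdin = matrix(0, 1, h6),
    aff.Wep = glorot(8L, h6), aff.Wed = glorot(8L, h6))
  for (t in seq_len(config$T)) {
    p[[paste0("aff.Wp", t)]] <- glorot(h6, h6)
    p[[paste0("aff.WQp", t)]] <- glorot(h6, h6)
    p[[paste0("aff.WKp", t)]] <- glorot(2L * h6, h6)
    p[[paste0("aff.WVp", t)]] <- glorot(2L * h6, h6)
    p[[paste0("aff.Wd", t)]] <- glorot(h6, h6)
    p[[paste0("aff.WQd", t)]] <- glorot(h6, h6)
    p[[paste0("aff.WKd", t)]] <- glorot(2L * h6, h6)
    p[[paste0("aff.WVd", t)]] <- glorot(2L * h6, h6)
  }
  p$aff.Wvp <- glorot(2L * h6, h6)
  p$aff.Watt <- glorot(2L * h6, 1L)
  p$aff.Wa1 <- glorot(3L * h6, 2L * h6)
  p$aff.ba1 <- matrix(0, 1, 2L * h6)
  p$aff.Wa2 <- glorot(2L * h6, 1L)
  p$aff.ba2 <- matrix(0, 1, 1)
  p
}

#' Affinity head forward pass (tape form)
#' @keywords internal
predict_affinity_f <- function(Hpocket, Hd, hetero, P, config,
                               train = FALSE) {
  slope <- config$leaky_slope
  hp <- ad_leaky_relu(nn_linear(Hpocket, P$aff.Wpin, P$aff.bpin), slope)
  hd <- ad_leaky_relu(nn_linear(Hd, P$aff.Wdin, P$aff.bdin), slope)
  ep2d <- ad_matmul(ad_leaf(hetero$feat_p2d, track = FALSE), P$aff.Wep)
  ed2p <- ad_matmul(ad_leaf(hetero$feat_d2p, track = FALSE), P$aff.Wed)
  np <- hetero$n_pocket; nd <- hetero$n_atoms
  d2p_atom <- hetero$edges_d2p[, 1]; d2p_res <- hetero$edges_d2p[, 2]
  p2d_res <- hetero$edges_p2d[, 1]; p2d_atom <- hetero$edges_p2d[, 2]
  for (t in seq_len(config$T)) {
    Wp <- P[[paste0("aff.Wp", t)]]; WQp <- P[[paste0("aff.WQp", t)]]
    WKp <- P[[paste0("aff.WKp", t)]]; WVp <- P[[paste0("aff.WVp", t)]]
    Wd <- P[[paste0("aff.Wd", t)]]; WQd <- P[[paste0("aff.WQd", t)]]
    WKd <- P[[paste0("aff.WKd", t)]]; WVd <- P[[paste0("aff.WVd", t)]]
    ## residue update: attends over incoming drug-atom messages
    cat_p <- ad_cbind(list(ad_gather_rows(hd, d2p_atom), ed2p))
    sc_p <- ad_smul(ad_rowsums(ad_mul(ad_gather_rows(ad_matmul(hp, WQp),
                                                     d2p_res),
                                      ad_matmul(cat_p, WKp))),
                    1 / sqrt(config$h6))
    a_p <- ad_segment_softmax(sc_p, d2p_res)
    agg_p <- ad_segment_sum(ad_mul_colvec(ad_matmul(cat_p, WVp), a_p),
                            d2p_res, np)
    ## atom update: attends over incoming residue messages
    cat_d <- ad_cbind(list(ad_gather_rows(hp, p2d_res), ep2d))
    sc_d <- ad_smul(ad_rowsums(ad_mul(ad_gather_rows(ad_matmul(hd, WQd),
                                                     p2d_atom),
                                      ad_matmul(cat_d, WKd))),
                    1 / sqrt(config$h6))
    a_d <- ad_segment_softmax(sc_d, p2d_atom)
    agg_d <- ad_segment_sum(ad_mul_colvec(ad_matmul(cat_d, WVd), a_d),
                            p2d_atom, nd)
    hp_new <- ad_leaky_relu(ad_add(ad_matmul(hp, Wp), agg_p), slope)
    hd_new <- ad_leaky_relu(ad_add(ad_matmul(hd, Wd), agg_d), slope)
    hp <- hp_new; hd <- hd_new
  }
  ones_p <- ad_leaf(matrix(1, 1, np), track = FALSE)
  ones_d <- ad_leaf(matrix(1, 1, nd), track = FALSE)
  u_p <- ad_matmul(ones_p, hp)
  u_d <- ad_matmul(ones_d, hd)
  ## pairwise attention-weighted complex vector
  if (config$pairwise == "all") {
    pr <- rep(seq_len(np), each = nd)
    pa <- rep(seq_len(nd), times = np)
  } else {
    pairs <- unique(rbind(cbind(p2d_res, p2d_atom),
                          cbind(d2p_res, d2p_atom)))
    pr <- pairs[, 1]; pa <- pairs[, 2]
  }
  ph <- ad_cbind(list(ad_gather_rows(hp, pr), ad_gather_rows(hd, pa)))
  alpha <- ad_segment_softmax(ad_matmul(ph, P$aff.Watt),
                              rep(1L, length(pr)))
  gvec <- ad_matmul(ad_transpose(alpha), ad_matmul(ph, P$aff.Wvp))
  feats <- ad_cbind(list(gvec, u_d, u_p))
  mlp2_f(feats, P$aff.Wa1, P$aff.ba1, P$aff.Wa2, P$aff.ba2, slope)
}

#' Predict binding affinity (p-affinity units)
#'
#' @param Hpocket N_pocket x h1 pocket residue embeddings.
#' @param Hd N_d x h3 drug atom embeddings.
#' @param hetero a \code{tribind_hetero_graph} over the same pocket and
#'   drug.
#' @param params affinity parameters ([init_affinity_params()]).
#' @param config a [model_config()].
#' @return scalar predicted p-affinity (-log10 molar).
#' @export
predict_affinity <- function(Hpocket, Hd, hetero, params,
                             config = model_config()) {
  if (!nrow(Hpocket) || !nrow(Hd)) stop("pocket and drug must be nonempty")
  if (nrow(Hpocket) != hetero$n_pocket || nrow(Hd) != hetero$n_atoms) {
    stop("encoding sizes do not match the heterogeneous graph")
  }
  ad_reset()
  P <- ad_wrap_params(params)
  out <- predict_affinity_f(ad_leaf(Hpocket, track = FALSE),
                            ad_leaf(Hd, track = FALSE), hetero, P, config)
  v <- as.numeric(out$value)
  ad_reset()
  v
}
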