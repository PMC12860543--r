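# Building blocks for the 3-D segmentation network.  Feature maps are
# [Nvox x C] matrices (voxel index x-fastest) with a `dims` attribute kept
# alongside; 3x3x3 convolutions go through im2col + BLAS gemm, transposed
# convolutions through the adjoint col2im path, and 1x1x1 convolutions
# (attention gates) are plain channel-matrix products.

.lrelu <- function(x, a = 0.1) {
  if (is.matrix(x)) cpp_lrelu(x, a) else pmax(x, 0) + a * pmin(x, 0)
}
# fused grad * d(lrelu)/dx
.lreluBwd <- function(pre, g, a = 0.1) cpp_lrelu_bwd(pre, g, a)
.lreluGrad <- function(pre, a = 0.1) (pre > 0) + a * (pre <= 0)
.sigmoid <- function(x) 1 / (1 + exp(-x))

.convLayer <- function(Cin, Cout, k = 3L, stride = 1L, pad = 1L, gain = 1) {
  fanIn <- Cin * k^3; fanOut <- Cout * k^3
  list(W = matrix(rnorm(fanIn * Cout, 0, gain * sqrt(2 / (fanIn + fanOut))), fanIn, Cout),
       b = rep(0.03, Cout), k = k, stride = stride, pad = pad,
       Cin = Cin, Cout = Cout, type = "conv")
}

# transposed conv: W is [Cup * k^3, Cdown]; forward scatters columns
.tconvLayer <- function(Cdown, Cup, k = 2L, stride = 2L, pad = 0L, gain = 1) {
  fanIn <- Cdown * k^3; fanOut <- Cup * k^3
  list(W = matrix(rnorm(Cup * k^3 * Cdown, 0, gain * sqrt(2 / (fanIn + fanOut))),
                  Cup * k^3, Cdown),
       b = rep(0.03, Cup), k = k, stride = stride, pad = pad,
       Cin = Cdown, Cout = Cup, type = "tconv")
}

.attLayer <- function(Cx, Cg, Fi) {
  gl <- function(fi, fo) matrix(rnorm(fi * fo, 0, sqrt(2 / (fi + fo))), fi, fo)
  list(Wx = gl(Cx, Fi), Wg = gl(Cg, Fi), bq = rep(0.03, Fi),
       psi = gl(Fi, 1L), bpsi = 0.03, Fi = Fi, type = "att")
}

.convOutDims <- function(dims, k, stride, pad) (dims + 2L * pad - k) %/% stride + 1L
.tconvOutDims <- function(dims, k, stride, pad) (dims - 1L) * stride + k - 2L * pad

.addBias <- function(m, b) m + rep(b, each = nrow(m))

# float32 kernels by default; options(ctless.fp32 = FALSE) selects the
# float64 reference path (used when checking gradients against finite
# differences, where float32 forward noise would swamp the quotients)
.fp32 <- function() isTRUE(getOption("ctless.fp32", TRUE))

.convFwd <- function(fm, dims, layer) {
  list(fm = cpp_conv3d_fwd(fm, dims, layer$W, layer$b, layer$k, layer$stride,
                           layer$pad, .fp32()),
       dims = .convOutDims(dims, layer$k, layer$stride, layer$pad))
}

.convBwd <- function(fm, dims, layer, dY) {
  cpp_conv3d_bwd(fm, dims, layer$W, layer$k, layer$stride, layer$pad, dY,
                 .fp32())
}

.tconvFwd <- function(fm, dims, layer) {
  list(fm = cpp_tconv3d_fwd(fm, dims, layer$W, layer$b, layer$k, layer$stride,
                            layer$pad, .fp32()),
       dims = .tconvOutDims(dims, layer$k, layer$stride, layer$pad))
}

.tconvBwd <- function(fm, dims, layer, dOut, outDims) {
  cpp_tconv3d_bwd(fm, dims, layer$W, layer$k, layer$stride, layer$pad, dOut,
                  .fp32())
}

# additive attention gate: alpha = sigmoid(psi' lrelu(Wx x + Wg g + bq));
# output is the skip feature x scaled voxelwise by alpha.
.attFwd <- function(x, g, layer) {
  qpre <- .addBias(x %*% layer$Wx + g %*% layer$Wg, layer$bq)
  q <- .lrelu(qpre)
  apre <- q %*% layer$psi + layer$bpsi
  alpha <- .sigmoid(apre)
  list(out = x * as.numeric(alpha), qpre = qpre, q = q, alpha = alpha)
}

.attBwd <- function(x, g, layer, cache, dOut) {
  dAlpha <- rowSums(dOut * x)
  dX <- dOut * as.numeric(cache$alpha)
  dApre <- dAlpha * as.numeric(cache$alpha) * (1 - as.numeric(cache$alpha))
  dPsi <- crossprod(cache$q, dApre)
  dQ <- dApre %*% t(layer$psi)
  dQpre <- dQ * .lreluGrad(cache$qpre)
  list(dWx = crossprod(x, dQpre), dWg = crossprod(g, dQpre),
       dbq = colSums(dQpre), dpsi = dPsi, dbpsi = sum(dApre),
       dX = dX + dQpre %*% t(layer$Wx), dG = dQpre %*% t(layer$Wg))
}

# recursive helpers over nested gradient trees (numeric leaves only);
# gradient trees mirror the trainable leaves of the parameter tree, so
# metadata entries (kernel size, stride, ...) are never touched.
.gzero <- function(g) { if (is.list(g)) lapply(g, .gzero) else g * 0 }

.gmap2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- .gmap2(f, a[[nm]], b[[nm]])
    return(out)
  }
  f(a, b)
}

.gsum <- function(g) { if (is.list(g)) sum(vapply(g, .gsum, numeric(1))) else sum(abs(g)) }
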