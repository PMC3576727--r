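// Hot loops of the imaging substrate: central-slice extraction and
// insertion on centred Fourier grids, and batched likelihood evaluation
// over orientation x translation grids (expressed as a complex GEMM).
//
// Conventions (shared with the R side):
//   - centred transforms: integer frequency k = index - N/2 (0-based);
//   - slice at image frequency (kx, ky) reads the volume transform at
//     q = R^T (kx, ky, 0)^T, i.e. the plane with normal R^T z;
//   - trilinear interpolation, no gridding kernel;
//   - a shift of the image by d multiplies its transform by
//     exp(-2*pi*i k.d / N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline std::complex<double> trilinear_read(const arma::cx_cube& V,
                                                  double x, double y,
                                                  double z) {
  const int n = V.n_rows;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
  if (x0 < 0 || y0 < 0 || z0 < 0 || x0 > n - 2 || y0 > n - 2 || z0 > n - 2)
    return std::complex<double>(0.0, 0.0);
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  std::complex<double> out(0.0, 0.0);
  for (int dz = 0; dz < 2; ++dz) {
    const double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy < 2; ++dy) {
      const double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx < 2; ++dx) {
        const double wx = dx ? fx : 1.0 - fx;
        out += (wx * wy * wz) * V(x0 + dx, y0 + dy, z0 + dz);
      }
    }
  }
  return out;
}

// Extract central Fourier slices for many rotations.
// V: centred complex transform (N^3); Rmats: npose x 9 (row-major per pose,
// R stored column-major as R(0,0),R(1,0),...); kx, ky: integer frequencies
// of the pixels to evaluate.  Returns npose x npix complex matrix.
// [[Rcpp::export]]
arma::cx_mat cpp_extract_slices(const arma::cx_cube& V,
                                const arma::mat& Rmats,
                                const arma::ivec& kx, const arma::ivec& ky) {
  const int n = V.n_rows;
  const double c = n / 2;
  const int npose = Rmats.n_rows;
  const int npix = kx.n_elem;
  arma::cx_mat out(npose, npix);
  for (int p = 0; p < npose; ++p) {
    const double r11 = Rmats(p, 0), r21 = Rmats(p, 1);
    const double r12 = Rmats(p, 3), r22 = Rmats(p, 4);
    for (int i = 0; i < npix; ++i) {
      // q = R^T (kx, ky, 0): rows of R dotted with k
      const double gx = kx[i], gy = ky[i];
      const double qx = r11 * gx + r21 * gy;
      const double qy = r12 * gx + r22 * gy;
      const double qz = Rmats(p, 6) * gx + Rmats(p, 7) * gy;
      out(p, i) = trilinear_read(V, qx + c, qy + c, qz + c);
    }
  }
  return out;
}

// Insert a batch of image transforms into a 3D accumulator by trilinear
// spreading.  imgs: N x N x m centred transforms; ctfs: N x N x m CTF
// values; Rmats: m x 9; shifts: m x 2 offsets (pixels) already applied to
// the images (they are removed here by the conjugate phase ramp);
// maxshell: insertion radius cap (in image shells); pad: oversampling of
// the target grid.  Returns num (CTF-weighted data sum) and wt (CTF^2
// sum), both on the padded (pad*N)^3 grid.
// [[Rcpp::export]]
List cpp_insert_slices(const arma::cx_cube& imgs, const arma::cube& ctfs,
                       const arma::mat& Rmats, const arma::mat& shifts,
                       const int maxshell, const int pad) {
  const int n = imgs.n_rows;
  const int m = imgs.n_slices;
  const int c = n / 2;
  const int np = pad * n;
  const int cp = np / 2;
  arma::cx_cube num(np, np, np, arma::fill::zeros);
  arma::cube wt(np, np, np, arma::fill::zeros);
  const double twopi_n = 2.0 * M_PI / n;
  for (int s = 0; s < m; ++s) {
    const double r11 = Rmats(s, 0), r21 = Rmats(s, 1);
    const double r12 = Rmats(s, 3), r22 = Rmats(s, 4);
    const double r13 = Rmats(s, 6), r23 = Rmats(s, 7);
    const double dx = shifts(s, 0), dy = shifts(s, 1);
    for (int j = 0; j < n; ++j) {
      const double gy = j - c;
      for (int i = 0; i < n; ++i) {
        const double gx = i - c;
        if (gx * gx + gy * gy > (double)maxshell * maxshell) continue;
        const double ctf = ctfs(i, j, s);
        // remove the offset: multiply by exp(+2 pi i k.d / N)
        const double ph = twopi_n * (gx * dx + gy * dy);
        const std::complex<double> val =
          imgs(i, j, s) * std::complex<double>(std::cos(ph), std::sin(ph));
        const std::complex<double> cval = ctf * val;
        const double w = ctf * ctf;
        const double qx = pad * (r11 * gx + r21 * gy) + cp;
        const double qy = pad * (r12 * gx + r22 * gy) + cp;
        const double qz = pad * (r13 * gx + r23 * gy) + cp;
        const int x0 = (int)std::floor(qx), y0 = (int)std::floor(qy),
                  z0 = (int)std::floor(qz);
        if (x0 < 0 || y0 < 0 || z0 < 0 || x0 > np - 2 || y0 > np - 2 ||
            z0 > np - 2)
          continue;
        const double fx = qx - x0, fy = qy - y0, fz = qz - z0;
        for (int dz = 0; dz < 2; ++dz) {
          const double wz = dz ? fz : 1.0 - fz;
          for (int dy2 = 0; dy2 < 2; ++dy2) {
            const double wy = dy2 ? fy : 1.0 - fy;
            for (int dx2 = 0; dx2 < 2; ++dx2) {
              const double wgt = (dx2 ? fx : 1.0 - fx) * wy * wz;
              num(x0 + dx2, y0 + dy2, z0 + dz) += wgt * cval;
              wt(x0 + dx2, y0 + dy2, z0 + dz) += wgt * w;
            }
          }
        }
      }
    }
  }
  return List::create(_["num"] = num, _["wt"] = wt);
}

// Batched posterior evaluation over a pose x shift grid.
//
// S:      npose x npix reference slices (complex)
// Sabs2:  npose x npix |S|^2 (real)
// Rmats:  npose x 9 rotation matrices
// X:      npix x nimg image transforms at the pixel list
// C:      npix x nimg CTF values
// iv:     npix weights = w_px / (2 sigma^2_shell) (half-plane weight folded)
// phases: npix x nshift translation phase ramps exp(+2 pi i k.d / N)
// shifts: nshift x 2 offsets (pixels)
// logprior: npose x nshift log prior weights (flat if empty)
// return_post: also return the full posterior (npose x nshift x nimg)
//
// Linear grid index for tie-breaking is column-major over (pose, shift).
// [[Rcpp::export]]
List cpp_align_batch(const arma::cx_mat& S, const arma::mat& Sabs2,
                     const arma::mat& Rmats, const arma::cx_mat& X,
                     const arma::mat& C, const arma::vec& iv,
                     const arma::cx_mat& phases, const arma::mat& shifts,
                     const arma::mat& logprior, const bool return_post) {
  const int npose = S.n_rows;
  const int npix = S.n_cols;
  const int nimg = X.n_cols;
  const int nshift = phases.n_cols;
  const bool has_prior = logprior.n_elem > 0;

  arma::uvec map_pose(nimg), map_shift(nimg);
  arma::vec log_evidence(nimg), max_post(nimg);
  arma::mat wR(nimg, 9), wT(nimg, 2);
  arma::cube post;
  if (return_post) post.set_size(npose, nshift, nimg);

  arma::cx_mat Zt(npix, nshift);
  arma::mat ll(npose, nshift);

  for (int j = 0; j < nimg; ++j) {
    // A_p = sum_px iv * C^2 |S_p|^2
    arma::vec cc = C.col(j) % C.col(j) % iv;
    arma::vec A = Sabs2 * cc;
    // Z = iv * C * conj(X); Zt = Z o conj(phase_t)
    arma::cx_vec Z = arma::conj(X.col(j)) % (C.col(j) % iv);
    for (int t = 0; t < nshift; ++t)
      Zt.col(t) = Z % arma::conj(phases.col(t));
    // loglik(p, t) = 2 Re(S Zt) - A_p  (+ image-constant term, dropped)
    ll = 2.0 * arma::real(S * Zt);
    ll.each_col() -= A;
    if (has_prior) ll += logprior;

    // log-sum-exp and posterior
    const double mx = ll.max();
    arma::mat g = arma::exp(ll - mx);
    const double Zsum = arma::accu(g);
    g /= Zsum;
    log_evidence[j] = mx + std::log(Zsum) -
      std::log((double)(npose * nshift));

    // MAP with lowest-linear-index tie break (column-major scan, strict >)
    arma::uword best = 0;
    double bestv = g[0];
    for (arma::uword k = 1; k < g.n_elem; ++k)
      if (g[k] > bestv + 0.0) { bestv = g[k]; best = k; }
    map_pose[j] = best % npose;
    map_shift[j] = best / npose;
    max_post[j] = bestv;

    // posterior-weighted rotation matrix and shift
    arma::vec gp = arma::sum(g, 1);        // marginal over shifts
    arma::rowvec gt = arma::sum(g, 0);     // marginal over poses
    wR.row(j) = (gp.t() * Rmats);
    wT.row(j) = gt * shifts;
    if (return_post) post.slice(j) = g;
  }
  List out = List::create(
    _["map_pose"] = map_pose + 1, _["map_shift"] = map_shift + 1,
    _["log_evidence"] = log_evidence, _["max_post"] = max_post,
    _["wR"] = wR, _["wT"] = wT);
  if (return_post) out["post"] = post;
  return out;
}

// Sum of anisotropic Gaussian blobs on an N^3 grid (phantom synthesis).
// centers: nb x 3 (0-based voxel coords), prec: nb x 9 precision matrices
// (column-major), amp: nb amplitudes.
// [[Rcpp::export]]
arma::cube cpp_blob_sum(const int n, const arma::mat& centers,
                        const arma::mat& prec, const arma::vec& amp) {
  arma::cube out(n, n, n, arma::fill::zeros);
  const int nb = centers.n_rows;
  for (int b = 0; b < nb; ++b) {
    const double cx = centers(b, 0), cy = centers(b, 1), cz = centers(b, 2);
    const double p11 = prec(b, 0), p21 = prec(b, 1), p31 = prec(b, 2);
    const double p22 = prec(b, 4), p32 = prec(b, 5), p33 = prec(b, 8);
    const double a = amp[b];
    for (int z = 0; z < n; ++z) {
      const double dz = z - cz;
      for (int y = 0; y < n; ++y) {
        const double dy = y - cy;
        for (int x = 0; x < n; ++x) {
          const double dx = x - cx;
          const double q = p11 * dx * dx + p22 * dy * dy + p33 * dz * dz +
            2.0 * (p21 * dx * dy + p31 * dx * dz + p32 * dy * dz);
          if (q < 30.0) out(x, y, z) += a * std::exp(-0.5 * q);
        }
      }
    }
  }
  return out;
}
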