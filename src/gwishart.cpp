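// Graph-constrained Wishart (G-Wishart) machinery.
//
// Target density on the cone of PD matrices compatible with a graph G:
//   p(Omega) ∝ |Omega|^{(delta-2)/2} exp(-tr(D Omega)/2),  Omega in M_G.
// Free entries are the diagonal plus the edge set. Updates are a block Gibbs
// scan over edge 2x2 cliques (Schur-complement Wishart draws) plus exact
// gamma draws for isolated vertices; the running inverse is maintained by
// rank-2 Woodbury updates and refreshed at the start of every scan.
// All randomness uses R's RNG.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Bartlett draw: W ~ Wishart(df, S) with scale S (mean df*S).
static mat rwish_bartlett(double df, const mat& S) {
  const uword p = S.n_rows;
  mat L = chol(S, "lower");
  mat A(p, p, fill::zeros);
  for (uword i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat LA = L * A;
  return LA * LA.t();
}

// [[Rcpp::export]]
arma::mat rwish_cpp(double df, const arma::mat& S) {
  return rwish_bartlett(df, S);
}

// One (or nscan) systematic block-Gibbs scans for the G-Wishart full
// conditional, in place on a single modality block.
// edges: m x 2 zero-based vertex pairs; isolated: zero-based vertices with
// no incident edge. Omega must start compatible with the graph and PD.
// [[Rcpp::export]]
arma::mat gwish_gibbs_cpp(arma::mat Omega, const arma::umat& edges,
                          const arma::uvec& isolated, const arma::mat& D,
                          double delta, int nscan) {
  const uword p = Omega.n_rows;
  const uword m = edges.n_rows;
  const mat I2 = eye(2, 2);

  for (int s = 0; s < nscan; ++s) {
    // exact gamma update for isolated vertices: |Omega| factorizes in w_jj
    for (uword k = 0; k < isolated.n_elem; ++k) {
      uword j = isolated(k);
      Omega(j, j) = R::rgamma(delta / 2.0, 2.0 / D(j, j));
    }
    if (m == 0) continue;

    mat Sigma = inv_sympd(Omega);
    for (uword e = 0; e < m; ++e) {
      uvec C = {edges(e, 0), edges(e, 1)};
      mat SigCC = Sigma.submat(C, C);
      mat OmCC = Omega.submat(C, C);
      // Schur complement of the rest: R = Omega_CC - inv(Sigma_CC)
      mat Rm = OmCC - inv_sympd(SigCC);
      mat Dcc = D.submat(C, C);
      mat Snew = rwish_bartlett(delta + 1.0, inv_sympd(Dcc));
      mat newCC = Snew + Rm;
      mat Delta = newCC - OmCC;
      Omega.submat(C, C) = newCC;
      // Woodbury: Sigma' = Sigma - Sigma[,C] M Sigma[C,],
      // M = Delta (I + Sigma_CC Delta)^{-1}
      mat M = Delta * inv(I2 + SigCC * Delta);
      mat ScolC = Sigma.cols(C);
      Sigma -= ScolC * M * ScolC.t();
    }
  }
  return Omega;
}

// Shared core: given per-row precision P and linear term b, one exact draw.
static void draw_row(mat& P, const vec& b, vec& z, mat& out, uword k) {
  const uword L = b.n_elem;
  mat U = chol(P);  // upper: P = U'U
  vec mu = solve(trimatu(U), solve(trimatl(U.t()), b));
  for (uword l = 0; l < L; ++l) z(l) = R::norm_rand();
  out.row(k) = (mu + solve(trimatu(U), z)).t();
}

// Batched Gaussian full-conditional draws for coefficient rows with
// per-observation weights (Polya-Gamma case). For output row k:
//   P_k = T' diag(w_k) T + diag(d_k),  b_k = Blin[k,]',
//   draw ~ N(P_k^{-1} b_k, P_k^{-1}).
// T: n x L design; Wts: q x n; Blin (precomputed T' kappa_k), Dprec: q x L.
// P0 is a shared base precision added to every row (e.g. the latent-factor
// prior plus the outcome-regression contribution in the Z update).
// [[Rcpp::export]]
arma::mat gibbs_rows_cpp(const arma::mat& T, const arma::mat& Wts,
                         const arma::mat& Blin, const arma::mat& Dprec,
                         const arma::mat& P0) {
  const uword n = T.n_rows, L = T.n_cols, q = Wts.n_rows;
  mat out(q, L);
  mat P(L, L);
  vec b(L), z(L), t(L);
  for (uword k = 0; k < q; ++k) {
    P = P0;
    for (uword i = 0; i < n; ++i) {
      const double w = Wts(k, i);
      for (uword l = 0; l < L; ++l) t(l) = T(i, l);
      for (uword l1 = 0; l1 < L; ++l1) {
        const double wt = w * t(l1);
        for (uword l2 = 0; l2 <= l1; ++l2) P(l1, l2) += wt * t(l2);
      }
    }
    for (uword l1 = 0; l1 < L; ++l1)
      for (uword l2 = l1 + 1; l2 < L; ++l2) P(l1, l2) = P(l2, l1);  // P0 symmetric
    P.diag() += Dprec.row(k).t();
    b = Blin.row(k).t();
    draw_row(P, b, z, out, k);
  }
  return out;
}

// Constant-weight variant (Gaussian modalities): P_k = w_k * TtT + P0 + diag(d_k).
// [[Rcpp::export]]
arma::mat gibbs_rows_constw_cpp(const arma::mat& TtT, const arma::vec& wscal,
                                const arma::mat& Blin, const arma::mat& Dprec,
                                const arma::mat& P0) {
  const uword L = TtT.n_rows, q = wscal.n_elem;
  mat out(q, L);
  mat P(L, L);
  vec b(L), z(L);
  for (uword k = 0; k < q; ++k) {
    P = wscal(k) * TtT + P0;
    P.diag() += Dprec.row(k).t();
    b = Blin.row(k).t();
    draw_row(P, b, z, out, k);
  }
  return out;
}
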