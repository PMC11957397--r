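// Hierarchical Bayesian PMF Gibbs sampler: fast core.
// Replicates the R reference sweep (R/engine.R) draw for draw: every latent
// vector update consumes exactly D standard normals from R's RNG after the
// Cholesky factorization of its full-conditional precision.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec draw_gaussian_cpp(const arma::mat& prec, const arma::vec& b) {
  arma::mat U;
  if (!arma::chol(U, prec)) {
    arma::mat jittered = prec +
      1e-10 * arma::eye<arma::mat>(prec.n_rows, prec.n_cols);
    if (!arma::chol(U, jittered))
      stop("full-conditional precision not positive definite");
  }
  arma::vec mn = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), b));
  arma::vec z(b.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z[i] = norm_rand();
  return mn + arma::solve(arma::trimatu(U), z);
}

struct Model {
  std::vector<arma::mat> Y, Dlt, S, T;
  std::vector<arma::ivec> parent;                 // 0-based, -1 = root
  std::vector<std::vector<arma::uvec>> children;  // 0-based indices at h+1
  std::vector<std::vector<arma::uvec>> obs_col, obs_row;  // observed indices
  int H, N, D;
  double sigma2, sigma_s2, sigma_t2;
};

static void update_t(Model& M, int h, int m) {
  int nk = (h < M.H - 1) ? (int)M.children[h][m].n_elem : 0;
  arma::mat prec = ((1.0 + nk) / M.sigma_t2) *
    arma::eye<arma::mat>(M.D, M.D);
  arma::vec b(M.D, arma::fill::zeros);
  const arma::uvec& obs = M.obs_col[h][m];
  if (obs.n_elem > 0) {
    arma::mat Sobs = M.S[h].rows(obs);
    arma::vec yobs = M.Y[h].col(m);
    yobs = yobs.elem(obs);
    prec += Sobs.t() * Sobs / M.sigma2;
    b += Sobs.t() * yobs / M.sigma2;
  }
  arma::vec pull(M.D, arma::fill::zeros);
  if (h > 0) pull += M.T[h - 1].row(M.parent[h][m]).t();
  if (nk > 0) pull += arma::sum(M.T[h + 1].rows(M.children[h][m]), 0).t();
  b += pull / M.sigma_t2;
  M.T[h].row(m) = draw_gaussian_cpp(prec, b).t();
}

static void update_s(Model& M, int h, int n) {
  int has_next = (h < M.H - 1) ? 1 : 0;
  arma::mat prec = ((1.0 + has_next) / M.sigma_s2) *
    arma::eye<arma::mat>(M.D, M.D);
  arma::vec b(M.D, arma::fill::zeros);
  const arma::uvec& obs = M.obs_row[h][n];
  if (obs.n_elem > 0) {
    arma::mat Tobs = M.T[h].rows(obs);
    arma::vec yobs = M.Y[h].row(n).t();
    yobs = yobs.elem(obs);
    prec += Tobs.t() * Tobs / M.sigma2;
    b += Tobs.t() * yobs / M.sigma2;
  }
  arma::vec pull(M.D, arma::fill::zeros);
  if (h > 0) pull += M.S[h - 1].row(n).t();
  if (has_next) pull += M.S[h + 1].row(n).t();
  b += pull / M.sigma_s2;
  M.S[h].row(n) = draw_gaussian_cpp(prec, b).t();
}

static void half_sweep(Model& M, bool top_down) {
  for (int i = 0; i < M.H; ++i) {
    int h = top_down ? i : (M.H - 1 - i);
    int Mh = (int)M.T[h].n_rows;
    for (int m = 0; m < Mh; ++m) update_t(M, h, m);
    for (int n = 0; n < M.N; ++n) update_s(M, h, n);
  }
}

static arma::rowvec objective_cpp(const Model& M,
                                  double lambda_s, double lambda_t) {
  arma::rowvec E(M.H, arma::fill::zeros);
  for (int h = 0; h < M.H; ++h) {
    arma::mat R = (M.Y[h] - M.S[h] * M.T[h].t()) % M.Dlt[h];
    E[h] = arma::accu(R % R);
    int Mh = (int)M.T[h].n_rows;
    for (int m = 0; m < Mh; ++m) {
      arma::rowvec par = (h > 0) ? M.T[h - 1].row(M.parent[h][m])
                                 : arma::rowvec(M.D, arma::fill::zeros);
      E[h] += lambda_t * arma::accu(arma::square(M.T[h].row(m) - par));
      if (h < M.H - 1) {
        const arma::uvec& kids = M.children[h][m];
        for (arma::uword k = 0; k < kids.n_elem; ++k)
          E[h] += lambda_t *
            arma::accu(arma::square(M.T[h].row(m) - M.T[h + 1].row(kids[k])));
      }
    }
    for (int n = 0; n < M.N; ++n) {
      arma::rowvec par = (h > 0) ? M.S[h - 1].row(n)
                                 : arma::rowvec(M.D, arma::fill::zeros);
      E[h] += lambda_s * arma::accu(arma::square(M.S[h].row(n) - par));
      if (h < M.H - 1)
        E[h] += lambda_s *
          arma::accu(arma::square(M.S[h].row(n) - M.S[h + 1].row(n)));
    }
  }
  return E;
}

// [[Rcpp::export]]
List gibbs_run_cpp(List y_levels, List delta_levels, List parent_t,
                   List children_t, List S_init, List T_init,
                   double sigma2, double sigma_s2, double sigma_t2,
                   int n_samples, int burn_in, int thin) {
  Model M;
  M.H = y_levels.size();
  M.sigma2 = sigma2; M.sigma_s2 = sigma_s2; M.sigma_t2 = sigma_t2;
  for (int h = 0; h < M.H; ++h) {
    M.Y.push_back(as<arma::mat>(y_levels[h]));
    M.Dlt.push_back(as<arma::mat>(delta_levels[h]));
    M.S.push_back(as<arma::mat>(S_init[h]));
    M.T.push_back(as<arma::mat>(T_init[h]));
    M.parent.push_back(as<arma::ivec>(parent_t[h]));
    List ch = children_t[h];
    std::vector<arma::uvec> kids(ch.size());
    for (int m = 0; m < ch.size(); ++m) {
      IntegerVector v = ch[m];
      arma::uvec u(v.size());
      for (int k = 0; k < v.size(); ++k) u[k] = (arma::uword)v[k];
      kids[m] = u;
    }
    M.children.push_back(kids);
    int Mh = (int)M.Y[h].n_cols, Nh = (int)M.Y[h].n_rows;
    std::vector<arma::uvec> oc(Mh), orow(Nh);
    for (int m = 0; m < Mh; ++m) oc[m] = arma::find(M.Dlt[h].col(m) > 0.5);
    for (int n = 0; n < Nh; ++n)
      orow[n] = arma::find(M.Dlt[h].row(n).t() > 0.5);
    M.obs_col.push_back(oc);
    M.obs_row.push_back(orow);
  }
  M.N = (int)M.Y[0].n_rows;
  M.D = (int)M.S[0].n_cols;
  double lambda_s = sigma2 / sigma_s2, lambda_t = sigma2 / sigma_t2;

  arma::mat objective(n_samples, M.H);
  List retained;
  for (int it = 1; it <= n_samples; ++it) {
    half_sweep(M, true);
    half_sweep(M, false);
    objective.row(it - 1) = objective_cpp(M, lambda_s, lambda_t);
    if (it > burn_in && (it - burn_in) % thin == 0) {
      List Sl(M.H), Tl(M.H);
      for (int h = 0; h < M.H; ++h) {
        Sl[h] = wrap(M.S[h]);
        Tl[h] = wrap(M.T[h]);
      }
      retained.push_back(List::create(Named("S") = Sl, Named("T") = Tl));
    }
  }
  return List::create(Named("retained") = retained,
                      Named("objective") = objective);
}
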