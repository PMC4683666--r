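// Fast empirical Bayesian LASSO engine: greedy basis selection under the
// normal-exponential-Gamma hierarchy. Mirrors the pure-R engine in
// R/eblasso.R (engine = "R"); the two are cross-checked in the test suite.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>

using namespace arma;

namespace {

struct State {
  const mat &X;          // residualized design, n x M
  const vec &xn2;        // column sums of squares
  const vec &Xty;        // X' ytil
  double yTy;
  int n;
  uvec act;              // active columns (0-based), in order of addition
  vec sig2;              // prior variances for act
  mat K;                 // X' X[, act], M x r
  mat Sg;                // posterior covariance on act
  vec mu;                // posterior mean on act
  vec s_all, q_all;      // full-C statistics for every candidate
  double s02, lam;

  State(const mat &X_, const vec &xn2_, const vec &Xty_, double yTy_,
        double s02_, double lam_)
      : X(X_), xn2(xn2_), Xty(Xty_), yTy(yTy_), n((int)X_.n_rows),
        K(X_.n_cols, 0), s02(s02_), lam(lam_) {}

  int r() const { return (int)act.n_elem; }

  void refresh() {
    int rr = r();
    if (rr) {
      mat G = K.rows(act);                       // r x r
      mat Si = diagmat(1.0 / sig2) + G / s02;
      Sg = inv_sympd(symmatu(Si));
      mu = Sg * Xty.elem(act) / s02;
      s_all = xn2 / s02 - sum((K * Sg) % K, 1) / (s02 * s02);
      q_all = (Xty - K * mu) / s02;
    } else {
      Sg.set_size(0, 0);
      mu.set_size(0);
      s_all = xn2 / s02;
      q_all = Xty / s02;
    }
  }

  // penalized marginal log-likelihood at the current state
  double pll() const {
    int rr = r();
    double quad, ldetC;
    if (rr) {
      quad = (yTy - dot(Xty.elem(act), mu)) / s02;
      double ldSg, sign;
      log_det(ldSg, sign, Sg);
      ldetC = n * std::log(s02) + accu(log(sig2)) - ldSg;
    } else {
      quad = yTy / s02;
      ldetC = n * std::log(s02);
    }
    return -0.5 * (ldetC + quad) - lam * accu(sig2);
  }

  // closed-form maximizer of the per-effect penalized likelihood
  double s2star(double S, double Q) const {
    if (lam > 0) {
      double u = (-S + std::sqrt(S * S + 8.0 * lam * Q * Q)) / (4.0 * lam);
      return (u - 1.0) / S;
    }
    return (Q * Q - S) / (S * S);
  }

  void add(uword j, double s2n) {
    vec kj = X.t() * X.col(j);
    double Sjj = 1.0 / (1.0 / s2n + s_all(j));
    double muj = Sjj * q_all(j);
    int rr = r();
    if (rr) {
      vec tmp = Sg * kj.elem(act);
      vec gv = (kj - K * tmp / s02) / s02;
      mat Sg2(rr + 1, rr + 1);
      Sg2.submat(0, 0, rr - 1, rr - 1) = Sg + (Sjj / (s02 * s02)) * (tmp * tmp.t());
      Sg2.submat(0, rr, rr - 1, rr) = -(Sjj / s02) * tmp;
      Sg2.submat(rr, 0, rr, rr - 1) = (-(Sjj / s02) * tmp).t();
      Sg2(rr, rr) = Sjj;
      Sg = Sg2;
      vec mu2(rr + 1);
      mu2.head(rr) = mu - muj * tmp / s02;
      mu2(rr) = muj;
      mu = mu2;
      s_all -= Sjj * square(gv);
      q_all -= muj * gv;
    } else {
      vec gv = kj / s02;
      Sg.set_size(1, 1);
      Sg(0, 0) = Sjj;
      mu.set_size(1);
      mu(0) = muj;
      s_all -= Sjj * square(gv);
      q_all -= muj * gv;
    }
    act.resize(rr + 1);
    act(rr) = j;
    sig2.resize(rr + 1);
    sig2(rr) = s2n;
    K.insert_cols(rr, kj);
  }

  void del(int pos) {
    vec Scol = Sg.col(pos);
    double Sjj = Sg(pos, pos), muj = mu(pos);
    vec gv = K * Scol / s02;
    s_all += square(gv) / Sjj;
    q_all += (muj / Sjj) * gv;
    Sg -= (Scol * Scol.t()) / Sjj;
    Sg.shed_row(pos);
    Sg.shed_col(pos);
    mu -= (muj / Sjj) * Scol;
    mu.shed_row(pos);
    act.shed_row(pos);
    sig2.shed_row(pos);
    K.shed_col(pos);
  }

  // sequential Gauss-Seidel passes over the in-model prior variances on the
  // active-set scale; every coordinate step is an exact maximization, so the
  // objective is non-decreasing. Full candidate statistics are refreshed once.
  void reestimate_block(int first, double inner_tol, int max_pass) {
    int rr = r();
    mat G = K.rows(act);
    vec s_act = s_all.elem(act);
    vec q_act = q_all.elem(act);
    // sweep only coordinates that are still moving; re-admit everything
    // periodically so cross-coupled coordinates are not frozen prematurely
    vec scol(rr), gv(rr);
    std::vector<int> moving(rr);
    for (int k = 0; k < rr; ++k)
      moving[k] = (k == 0) ? first : (k <= first ? k - 1 : k);
    for (int pass = 0; pass < max_pass; ++pass) {
      if (moving.empty()) {
        // recheck all coordinates cheaply; collect the ones still moving
        for (int pos = 0; pos < rr; ++pos) {
          double den = std::max(1.0 - sig2(pos) * s_act(pos), 1e-12);
          double Sj = std::max(s_act(pos) / den, 1e-300);
          double Qj = q_act(pos) / den;
          if (Qj * Qj - Sj - 2.0 * lam <= 0) continue;
          double s2n = s2star(Sj, Qj);
          if (s2n <= 0) continue;
          if (std::fabs(s2n - sig2(pos)) >= inner_tol) moving.push_back(pos);
        }
        if (moving.empty()) break;
      }
      std::vector<int> nxt;
      for (int pos : moving) {
        double den = std::max(1.0 - sig2(pos) * s_act(pos), 1e-12);
        double Sj = std::max(s_act(pos) / den, 1e-300);
        double Qj = q_act(pos) / den;
        if (Qj * Qj - Sj - 2.0 * lam <= 0) continue;
        double s2n = s2star(Sj, Qj);
        if (s2n <= 0) continue;
        double a_old = 1.0 / sig2(pos), a_new = 1.0 / s2n;
        if (std::fabs(a_new - a_old) > 1e-300) {
          // allocation-free rank-1 updates on the active-set state
          double kap = 1.0 / (Sg(pos, pos) + 1.0 / (a_new - a_old));
          std::memcpy(scol.memptr(), Sg.colptr(pos), rr * sizeof(double));
          gv = G * scol;
          double kmu = kap * mu(pos);
          const double *g = gv.memptr(), *sc = scol.memptr();
          double *sa = s_act.memptr(), *qa = q_act.memptr(), *m = mu.memptr();
          double inv2 = 1.0 / (s02 * s02), inv1 = 1.0 / s02;
          for (int i = 0; i < rr; ++i) {
            sa[i] += kap * g[i] * g[i] * inv2;
            qa[i] += kmu * g[i] * inv1;
            m[i] -= kmu * sc[i];
          }
          double *sg = Sg.memptr();
          for (int c = 0; c < rr; ++c) {
            double f = kap * sc[c];
            double *col = sg + (size_t)c * rr;
            for (int i = 0; i < rr; ++i) col[i] -= f * sc[i];
          }
        }
        if (std::fabs(s2n - sig2(pos)) >= inner_tol) nxt.push_back(pos);
        sig2(pos) = s2n;
      }
      moving.swap(nxt);
    }
    s_all = xn2 / s02 - sum((K * Sg) % K, 1) / (s02 * s02);
    q_all = (Xty - K * mu) / s02;
  }
};

} // namespace

// [[Rcpp::export(name = ".eb_engine_cpp")]]
Rcpp::List eb_engine_cpp(const arma::mat &X, const arma::vec &ytil,
                         const arma::uvec &candidate, double a_gamma,
                         double b_gamma, double lambda_init, bool est_lam,
                         double s02_init, bool est_s02, double tol,
                         double inner_tol, int max_iter, int max_inner) {
  // est_s02 / est_lam may be switched off by the freeze schedule below
  const int n = (int)X.n_rows;
  const int M = (int)X.n_cols;
  vec xn2 = sum(square(X), 0).t();
  vec Xty = X.t() * ytil;
  double yTy = dot(ytil, ytil);
  double vy = yTy / std::max(1, n - 1);
  const double gain_tol = 1e-9;

  State st(X, xn2, Xty, yTy, s02_init, lambda_init);
  st.refresh();
  // two-stage schedule: adapt the hyperparameters for a burn-in, then
  // freeze them and converge the basis sweep exactly under fixed values
  // (the joint greedy/EM iteration can cycle indefinitely on borderline
  // effects otherwise)
  const int freeze_at = 25;

  Rcpp::List trace_out;
  bool converged = false, hit_inner = false, hit_outer = false;
  int stationary = 0;
  int outer_it = 0;

  while (true) {
    ++outer_it;
    st.refresh();
    std::vector<double> trace_i;
    bool just_reestimated = false;
    int inner_it = 0;
    while (true) {
      ++inner_it;
      int rr = st.r();
      vec S = st.s_all, Q = st.q_all;
      for (int k = 0; k < rr; ++k) {
        uword j = st.act(k);
        double den = std::max(1.0 - st.sig2(k) * st.s_all(j), 1e-12);
        S(j) = st.s_all(j) / den;
        Q(j) = st.q_all(j) / den;
      }
      S = clamp(S, 1e-300, datum::inf);
      // score every candidate action
      double gbest = -datum::inf;
      int best = -1, best_pos = -1;
      int action = 0; // 1 add, 2 reestimate, 3 delete
      std::vector<char> inm(M, 0);
      std::vector<int> posof(M, -1);
      for (int k = 0; k < rr; ++k) {
        inm[st.act(k)] = 1;
        posof[st.act(k)] = k;
      }
      auto ell = [&](double s2, double Sj, double Qj) {
        return 0.5 * (-std::log1p(s2 * Sj) +
                      Qj * Qj * s2 / (1.0 + s2 * Sj)) - st.lam * s2;
      };
      for (int j = 0; j < M; ++j) {
        if (!candidate(j) && !inm[j]) continue;
        double Sj = S(j), Qj = Q(j);
        double theta = Qj * Qj - Sj - 2.0 * st.lam;
        double g;
        int a;
        if (theta > 0) {
          double s2n = st.s2star(Sj, Qj);
          if (s2n <= 0) {
            if (!inm[j]) continue;
            g = -ell(st.sig2(posof[j]), Sj, Qj);
            a = 3;
          } else if (inm[j]) {
            g = ell(s2n, Sj, Qj) - ell(st.sig2(posof[j]), Sj, Qj);
            a = 2;
          } else {
            if (rr >= n - 2) continue;   // model-size cap
            g = ell(s2n, Sj, Qj);
            a = 1;
          }
        } else if (inm[j]) {
          g = -ell(st.sig2(posof[j]), Sj, Qj);
          a = 3;
        } else {
          continue;
        }
        if (g > gbest) {
          gbest = g;
          best = j;
          best_pos = posof[j];
          action = a;
        }
      }
      if (best < 0 || gbest <= gain_tol) break;
      bool small_step = false;
      if (action == 2) {
        // mid-run blocks take a few monotone passes only; the final
        // stationarity check (a second consecutive re-estimate proposal)
        // converges the prior variances fully
        st.reestimate_block(best_pos, inner_tol, just_reestimated ? 300 : 10);
        small_step = just_reestimated;
        just_reestimated = true;
      } else if (action == 1) {
        just_reestimated = false;
        double s2n = st.s2star(S(best), Q(best));
        st.add((uword)best, s2n);
      } else {
        just_reestimated = false;
        st.del(best_pos);
      }
      trace_i.push_back(st.pll());
      if (small_step) break;
      // the first sweeps are truncated: lambda and sigma0^2 are re-estimated
      // from a partial model before the model can balloon under the
      // permissive initial penalty
      if (inner_it >= 30 * outer_it && outer_it < max_iter / 2) break;
      if (inner_it >= max_inner) {
        hit_inner = true;
        break;
      }
    }
    trace_out.push_back(Rcpp::NumericVector(trace_i.begin(), trace_i.end()));

    st.refresh();
    if (outer_it >= freeze_at) { est_s02 = false; est_lam = false; }
    int rr = st.r();
    double s02_new, lam_new;
    if (rr) {
      vec resid = ytil - X.cols(st.act) * st.mu;
      double sg = 0;
      for (int k = 0; k < rr; ++k) sg += 1.0 - st.Sg(k, k) / st.sig2(k);
      s02_new = est_s02 ? dot(resid, resid) / std::max(1.0, n - sg) : st.s02;
      // geometric damping: the raw update can oscillate between a
      // ballooning model (huge lambda) and an empty one (lambda 0) on
      // noise-dominated data; stepping half-way in log scale adapts fast
      // across magnitudes and still settles
      if (est_lam) {
        double raw = std::max(0.0, (rr - 1 + a_gamma) / (accu(st.sig2) + b_gamma));
        lam_new = (raw > 1e-12) ? std::sqrt(st.lam * raw) : st.lam / 2.0;
      } else lam_new = st.lam;
    } else {
      s02_new = est_s02 ? yTy / n : st.s02;
      if (est_lam) {
        double raw = std::max(0.0, (a_gamma - 1.0) / b_gamma);
        lam_new = (raw > 1e-12) ? std::sqrt(st.lam * raw) : st.lam / 2.0;
      } else lam_new = st.lam;
    }
    double dl = std::fabs(lam_new - st.lam) / std::max(st.lam, 1e-10);
    double ds = std::fabs(s02_new - st.s02) / std::max(st.s02, 1e-300);
    if (ds < tol && dl < tol) {
      // keep the state the final sweep converged under, so the reported
      // retention criterion is exact at the reported hyperparameters
      converged = true;
      break;
    }
    // stationarity fallback: borderline effects entering and leaving keep
    // lambda jittering at the percent level without changing inference
    if (ds < tol && dl < 100.0 * tol) ++stationary; else stationary = 0;
    if (stationary >= 5) {
      converged = true;
      break;
    }
    st.s02 = std::max(s02_new, 1e-12 * vy);
    st.lam = lam_new;
    if (outer_it >= max_iter) {
      hit_outer = true;
      break;
    }
  }

  st.refresh();
  int rr = st.r();
  vec S = st.s_all, Q = st.q_all;
  for (int k = 0; k < rr; ++k) {
    uword j = st.act(k);
    double den = std::max(1.0 - st.sig2(k) * st.s_all(j), 1e-12);
    S(j) = st.s_all(j) / den;
    Q(j) = st.q_all(j) / den;
  }

  return Rcpp::List::create(
      Rcpp::Named("act") = Rcpp::IntegerVector(st.act.begin(), st.act.end()),
      Rcpp::Named("sig2") = st.sig2, Rcpp::Named("Sigma") = st.Sg,
      Rcpp::Named("mu") = st.mu, Rcpp::Named("S") = S, Rcpp::Named("Q") = Q,
      Rcpp::Named("sigma02") = st.s02, Rcpp::Named("lambda") = st.lam,
      Rcpp::Named("loglik") = st.pll(), Rcpp::Named("trace") = trace_out,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("outer_iterations") = outer_it,
      Rcpp::Named("hit_inner") = hit_inner,
      Rcpp::Named("hit_outer") = hit_outer);
}
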