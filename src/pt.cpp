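// Parallel-tempering core: replica-exchange Metropolis over a box-constrained
// parameter space, used as a global maximum-likelihood optimizer.
//
// Chains hold their state in "sampling space": parameters flagged log-scale
// are random-walked on the log of their value (matching log-space
// initialization), all others on the value itself.  The invariant measure of
// chain k is exp(logL(p)/T_k) dp, so acceptance for log-scale coordinates
// carries the change-of-variable term sum(u' - u).  The best *untempered*
// log-likelihood over every evaluated point (initial states and all
// proposals, accepted or not) is tracked and returned.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();

inline double softplus(double w) {
  return w > 33.0 ? w : std::log1p(std::exp(w));
}

struct Objective {
  int kind;  // 0 = simple PP model, 1 = expanded PP model, 2 = quadratic
  std::vector<double> td, tdp, pp;
  double inv2s2;
  std::vector<double> A;  // row-major d x d (quadratic curvature)
  std::vector<double> center;
  int d;
};

double obj_loglik(const Objective& o, const double* p) {
  if (o.kind == 2) {
    double q = 0.0;
    for (int i = 0; i < o.d; ++i) {
      double acc = 0.0;
      for (int j = 0; j < o.d; ++j)
        acc += o.A[i * o.d + j] * (p[j] - o.center[j]);
      q += (p[i] - o.center[i]) * acc;
    }
    return -0.5 * q;
  }
  const double k1m = p[0], k3 = p[1], beta = p[2], C = p[3];
  const double ia = 1.0 / p[4], delta = p[5];
  const double k4 = (o.kind == 1) ? p[6] : 0.0;
  const double lr = std::log(k1m / k3), bk3 = beta * k3;
  double sse = 0.0;
  const size_t n = o.td.size();
  for (size_t i = 0; i < n; ++i) {
    double te = o.td[i] + C + (o.kind == 1 ? k4 * o.tdp[i] : 0.0);
    double v = k3 * te - softplus(lr + bk3 * te) / beta;
    double r = o.pp[i] - (v * ia + delta);
    sse += r * r;
  }
  double ll = -sse * o.inv2s2;
  return std::isfinite(ll) ? ll : NEG_INF;
}

Objective make_objective(const List& spec) {
  Objective o;
  o.kind = as<int>(spec["kind"]);
  if (o.kind == 2) {
    NumericMatrix A = spec["A"];
    NumericVector c = spec["center"];
    o.d = c.size();
    o.A.assign(A.begin(), A.end());
    // NumericMatrix is column-major; the quadratic form is symmetric so
    // row/column order does not matter, but keep it explicit:
    std::vector<double> rowmajor(o.d * o.d);
    for (int i = 0; i < o.d; ++i)
      for (int j = 0; j < o.d; ++j) rowmajor[i * o.d + j] = A(i, j);
    o.A = rowmajor;
    o.center.assign(c.begin(), c.end());
    o.inv2s2 = 0.0;
  } else {
    NumericVector td = spec["t_dia"], pp = spec["pp"];
    o.td.assign(td.begin(), td.end());
    o.pp.assign(pp.begin(), pp.end());
    if (o.kind == 1) {
      NumericVector tdp = spec["t_dia_prev"];
      o.tdp.assign(tdp.begin(), tdp.end());
    }
    double sigma = as<double>(spec["sigma"]);
    o.inv2s2 = 1.0 / (2.0 * sigma * sigma);
    o.d = (o.kind == 1) ? 7 : 6;
  }
  return o;
}

}  // namespace

// [[Rcpp::export]]
double obj_loglik_cpp(List objective, NumericVector p) {
  Objective o = make_objective(objective);
  return obj_loglik(o, REAL(p));
}

// [[Rcpp::export]]
List pt_core(NumericMatrix init,        // n_chains x d, natural scale
             NumericVector temps,       // length n_chains, T[0] == 1
             NumericVector prop_sd,     // length d, in sampling space
             LogicalVector log_scale,   // length d
             double lower, double upper,
             int n_sweeps, int swap_interval,
             List objective, int seed, int thin_cold) {
  const int nc = init.nrow(), d = init.ncol();
  Objective obj = make_objective(objective);
  const double log_upper = std::log(upper);

  // chain state in sampling space + cached untempered log-likelihood
  std::vector<std::vector<double>> u(nc, std::vector<double>(d));
  std::vector<double> ll(nc);
  std::vector<double> pbuf(d);
  auto to_p = [&](const std::vector<double>& uu, std::vector<double>& p) {
    for (int j = 0; j < d; ++j) p[j] = log_scale[j] ? std::exp(uu[j]) : uu[j];
  };

  double best_ll = NEG_INF;
  std::vector<double> best_p(d);

  for (int k = 0; k < nc; ++k) {
    for (int j = 0; j < d; ++j)
      u[k][j] = log_scale[j] ? std::log(init(k, j)) : init(k, j);
    to_p(u[k], pbuf);
    ll[k] = obj_loglik(obj, pbuf.data());
    if (ll[k] > best_ll) { best_ll = ll[k]; best_p = pbuf; }
  }

  // one RNG per chain so the cold chain's stream is independent of chain
  // count; a separate stream drives swap decisions
  std::vector<std::mt19937_64> rng;
  for (int k = 0; k < nc; ++k) {
    std::seed_seq ss{seed, k + 1};
    rng.emplace_back(ss);
  }
  std::seed_seq ss_swap{seed, -7};
  std::mt19937_64 rng_swap(ss_swap);
  std::normal_distribution<double> rnorm(0.0, 1.0);
  std::uniform_real_distribution<double> runif(0.0, 1.0);

  std::vector<long> acc(nc, 0), prop_n(nc, 0);
  std::vector<long> swap_acc(std::max(nc - 1, 0), 0),
      swap_try(std::max(nc - 1, 0), 0);

  int n_rec = (thin_cold > 0) ? n_sweeps / thin_cold : 0;
  NumericMatrix cold(n_rec, d);
  int rec = 0, swap_parity = 0;

  std::vector<double> uprop(d);
  for (int s = 1; s <= n_sweeps; ++s) {
    for (int k = 0; k < nc; ++k) {
      double jac = 0.0;
      bool in_box = true;
      for (int j = 0; j < d; ++j) {
        double step = prop_sd[j] > 0.0 ? prop_sd[j] * rnorm(rng[k]) : 0.0;
        double v = u[k][j] + step;
        uprop[j] = v;
        if (log_scale[j]) {
          if (v >= log_upper) in_box = false;
          jac += v - u[k][j];
        } else if (v <= lower || v >= upper) {
          in_box = false;
        }
      }
      ++prop_n[k];
      if (!in_box) continue;
      to_p(uprop, pbuf);
      double llp = obj_loglik(obj, pbuf.data());
      if (llp > best_ll) { best_ll = llp; best_p = pbuf; }
      double lr = (llp - ll[k]) / temps[k] + jac;
      if (lr >= 0.0 || std::log(runif(rng[k])) < lr) {
        u[k] = uprop;
        ll[k] = llp;
        ++acc[k];
      }
    }
    if (swap_interval > 0 && nc > 1 && s % swap_interval == 0) {
      for (int k = swap_parity; k + 1 < nc; k += 2) {
        ++swap_try[k];
        double lr = (1.0 / temps[k] - 1.0 / temps[k + 1]) * (ll[k + 1] - ll[k]);
        if (lr >= 0.0 || std::log(runif(rng_swap)) < lr) {
          std::swap(u[k], u[k + 1]);
          std::swap(ll[k], ll[k + 1]);
          ++swap_acc[k];
        }
      }
      swap_parity = 1 - swap_parity;
    }
    if (thin_cold > 0 && s % thin_cold == 0 && rec < n_rec) {
      to_p(u[0], pbuf);
      for (int j = 0; j < d; ++j) cold(rec, j) = pbuf[j];
      ++rec;
    }
    if (s % 8192 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix state(nc, d);
  NumericVector state_ll(nc);
  for (int k = 0; k < nc; ++k) {
    to_p(u[k], pbuf);
    for (int j = 0; j < d; ++j) state(k, j) = pbuf[j];
    state_ll[k] = ll[k];
  }
  return List::create(
      _["best_p"] = NumericVector(best_p.begin(), best_p.end()),
      _["best_loglik"] = best_ll, _["state"] = state,
      _["state_loglik"] = state_ll,
      _["accept"] = NumericVector(acc.begin(), acc.end()),
      _["proposals"] = NumericVector(prop_n.begin(), prop_n.end()),
      _["swap_accept"] = NumericVector(swap_acc.begin(), swap_acc.end()),
      _["swap_attempts"] = NumericVector(swap_try.begin(), swap_try.end()),
      _["cold_samples"] = cold);
}
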