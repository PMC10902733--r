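// Probit Bayesian additive regression trees on binomial cell counts.
//
// Sum-of-trees model f(x) = sum_j g(x; T_j, M_j) with the standard tree
// regularisation prior P(split at depth d) = alpha (1+d)^-beta and
// conjugate Gaussian leaf values mu ~ N(0, sigma_mu^2),
// sigma_mu = 3 / (k sqrt(m)).  Binary outcomes enter through Albert-Chib
// latent variables z ~ N(offset + f(x), 1) truncated by the outcome, so
// the residual variance is fixed at 1 and leaf values integrate out in
// closed form for the Metropolis-Hastings tree moves (grow/prune/change).
//
// Rows are binomial cells (trials, successes) sharing one covariate
// vector; all latent records of a cell travel together through every tree,
// so only the per-cell sum of latents is needed.  That sum is drawn
// exactly (record by record) for small cells and by a normal
// approximation to the sum of truncated normals for large ones.
// Expanded Bernoulli data is the special case trials = 1.
//
// Uses R's RNG, so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  Node *l = nullptr, *r = nullptr, *parent = nullptr;
  int var = -1;          // split variable (internal nodes)
  int cut = -1;          // index into cutpoints[var]
  double mu = 0.0;       // leaf value
  int depth = 0;
  int idx = -1;          // scratch leaf index
  bool is_leaf() const { return l == nullptr; }
};

void delete_tree(Node *n) {
  if (!n) return;
  delete_tree(n->l);
  delete_tree(n->r);
  delete n;
}

void collect_leaves(Node *n, std::vector<Node *> &out) {
  if (n->is_leaf()) { n->idx = (int)out.size(); out.push_back(n); return; }
  collect_leaves(n->l, out);
  collect_leaves(n->r, out);
}

void collect_leaf_parents(Node *n, std::vector<Node *> &out) {
  if (n->is_leaf()) return;
  if (n->l->is_leaf() && n->r->is_leaf()) { out.push_back(n); return; }
  collect_leaf_parents(n->l, out);
  collect_leaf_parents(n->r, out);
}

struct Cutpoints {
  // cut value c sends x <= c left, x > c right
  std::vector<std::vector<double>> cuts;
};

Node *leaf_for(Node *root, const double *xrow, int stride,
               const Cutpoints &cp) {
  Node *n = root;
  while (!n->is_leaf())
    n = (xrow[(size_t)n->var * stride] <= cp.cuts[n->var][n->cut]) ? n->l : n->r;
  return n;
}

// log of the leaf marginal likelihood terms that do not cancel between
// competing partitions of the same observations (sigma = 1); n counts
// latent records, not cells
inline double leaf_lml(double n, double S, double s2mu) {
  return 0.5 * std::log(1.0 / (1.0 + n * s2mu)) +
         0.5 * s2mu * S * S / (1.0 + n * s2mu);
}

inline double log_psplit(int depth, double alpha, double beta) {
  return std::log(alpha) - beta * std::log(1.0 + depth);
}

inline double log_pnosplit(int depth, double alpha, double beta) {
  return std::log(1.0 - alpha * std::pow(1.0 + depth, -beta));
}

// valid cut indices c with lo <= cuts[c] < hi, so both children are
// non-empty given the node's data range [lo, hi]
struct CutRange { int first = 0, count = 0; };

CutRange valid_cuts(const std::vector<double> &cuts, double lo, double hi) {
  CutRange r;
  if (cuts.empty() || lo >= hi) return r;
  int a = (int)(std::lower_bound(cuts.begin(), cuts.end(), lo) - cuts.begin());
  int b = (int)(std::lower_bound(cuts.begin(), cuts.end(), hi) - cuts.begin());
  r.first = a;
  r.count = b - a;
  return r;
}

int sample_int(int n) { return (int)std::floor(unif_rand() * n) % n; }

// one draw from N(mean, 1) truncated to the positive or negative half line
double rtnorm(double mean, bool positive) {
  double u = unif_rand();
  double p0 = R::pnorm(0.0, mean, 1.0, 1, 0);
  double p = positive ? p0 + u * (1.0 - p0) : u * p0;
  p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
  return R::qnorm(p, mean, 1.0, 1, 0);
}

// mean and variance of N(m, 1) truncated to a half line
inline void tnorm_moments(double m, bool positive, double &mean, double &var) {
  if (positive) {
    double lam = std::exp(R::dnorm(m, 0.0, 1.0, 1) -
                          R::pnorm(m, 0.0, 1.0, 1, 1));
    mean = m + lam;
    var = 1.0 - m * lam - lam * lam;
  } else {
    double lam = std::exp(R::dnorm(m, 0.0, 1.0, 1) -
                          R::pnorm(-m, 0.0, 1.0, 1, 1));
    mean = m - lam;
    var = 1.0 + m * lam - lam * lam;
  }
  if (var < 1e-10) var = 1e-10;
}

// draw the sum of `count` iid truncated normals around m: exact for small
// counts, CLT approximation for large ones
double rtnorm_sum(double m, int count, bool positive) {
  if (count <= 0) return 0.0;
  if (count <= 32) {
    double s = 0.0;
    for (int i = 0; i < count; ++i) s += rtnorm(m, positive);
    return s;
  }
  double mean, var;
  tnorm_moments(m, positive, mean, var);
  return count * mean + std::sqrt(count * var) * norm_rand();
}

} // namespace

// [[Rcpp::export]]
List bart_probit_cpp(NumericMatrix X, IntegerVector trials,
                     IntegerVector successes, NumericMatrix Xpred,
                     int ntree, int nburn, int ndraw, int thin,
                     double alpha, double beta, double k, int numcut,
                     double offset, bool verbose) {
  const int n = X.nrow(), p = X.ncol(), m = Xpred.nrow();
  if ((int)trials.size() != n || (int)successes.size() != n)
    stop("trials/successes length must match nrow(X)");
  for (int i = 0; i < n; ++i) {
    if (trials[i] <= 0) stop("all cells must have at least one trial");
    if (successes[i] < 0 || successes[i] > trials[i])
      stop("successes must lie in [0, trials]");
  }
  if (Xpred.ncol() != p) stop("Xpred must have the same columns as X");

  const double s2mu = std::pow(3.0 / (k * std::sqrt((double)ntree)), 2);

  // cutpoint grids: midpoints of consecutive unique values, thinned to numcut
  Cutpoints cp;
  cp.cuts.resize(p);
  for (int j = 0; j < p; ++j) {
    std::vector<double> v(n);
    for (int i = 0; i < n; ++i) v[i] = X(i, j);
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
    std::vector<double> mids;
    for (size_t t = 0; t + 1 < v.size(); ++t)
      mids.push_back(0.5 * (v[t] + v[t + 1]));
    if ((int)mids.size() > numcut) {
      std::vector<double> sub;
      for (int t = 0; t < numcut; ++t)
        sub.push_back(mids[(size_t)((t + 0.5) * mids.size() / numcut)]);
      mids = sub;
    }
    cp.cuts[j] = mids;
  }

  RNGScope scope;

  std::vector<Node *> trees(ntree);
  for (int j = 0; j < ntree; ++j) trees[j] = new Node();

  // per-cell quantities; fits/fhat are per latent record (shared by a cell)
  std::vector<std::vector<double>> fits(ntree, std::vector<double>(n, 0.0));
  std::vector<double> fhat(n, 0.0), S(n), w(n);
  for (int i = 0; i < n; ++i) w[i] = (double)trials[i];
  for (int i = 0; i < n; ++i)
    S[i] = rtnorm_sum(offset, successes[i], true) +
           rtnorm_sum(offset, trials[i] - successes[i], false);

  NumericMatrix pred_draws(ndraw, m);
  NumericMatrix train_draws(ndraw, n);
  int accept = 0, proposals = 0;

  std::vector<double> R(n);   // per-cell summed partial residual
  std::vector<int> leaf_of(n);

  const int total_iter = nburn + ndraw * thin;
  int kept = 0;

  for (int iter = 0; iter < total_iter; ++iter) {
    for (int j = 0; j < ntree; ++j) {
      Node *root = trees[j];
      for (int i = 0; i < n; ++i)
        R[i] = S[i] - w[i] * (offset + fhat[i] - fits[j][i]);

      // leaf membership
      std::vector<Node *> leaves;
      collect_leaves(root, leaves);
      const int L = (int)leaves.size();
      std::vector<std::vector<int>> obs(L);
      for (int i = 0; i < n; ++i) {
        Node *nd = leaf_for(root, &X(i, 0), n, cp);
        leaf_of[i] = nd->idx;
        obs[nd->idx].push_back(i);
      }

      double u_move = unif_rand();
      bool structure_changed = false;
      ++proposals;

      if (u_move < 0.25 || root->is_leaf()) {
        // ---- GROW ----
        std::vector<int> growable;
        for (int l = 0; l < L; ++l) if (!obs[l].empty()) growable.push_back(l);
        if (!growable.empty()) {
          int gi = growable[sample_int((int)growable.size())];
          Node *leaf = leaves[gi];
          std::vector<double> lo(p, R_PosInf), hi(p, R_NegInf);
          for (int t : obs[gi]) {
            for (int jj = 0; jj < p; ++jj) {
              double xv = X(t, jj);
              if (xv < lo[jj]) lo[jj] = xv;
              if (xv > hi[jj]) hi[jj] = xv;
            }
          }
          std::vector<int> vars;
          std::vector<CutRange> ranges(p);
          for (int jj = 0; jj < p; ++jj) {
            ranges[jj] = valid_cuts(cp.cuts[jj], lo[jj], hi[jj]);
            if (ranges[jj].count > 0) vars.push_back(jj);
          }
          if (!vars.empty()) {
            int var = vars[sample_int((int)vars.size())];
            int cut = ranges[var].first + sample_int(ranges[var].count);
            double cval = cp.cuts[var][cut];
            double nl = 0, sl = 0, nr = 0, sr = 0;
            for (int t : obs[gi]) {
              if (X(t, var) <= cval) { nl += w[t]; sl += R[t]; }
              else { nr += w[t]; sr += R[t]; }
            }
            double ntot = nl + nr, stot = sl + sr;
            int d = leaf->depth;
            double log_lik = leaf_lml(nl, sl, s2mu) + leaf_lml(nr, sr, s2mu) -
                             leaf_lml(ntot, stot, s2mu);
            double log_prior = log_psplit(d, alpha, beta) +
                               2.0 * log_pnosplit(d + 1, alpha, beta) -
                               log_pnosplit(d, alpha, beta);
            // reverse move is a prune of the new leaf-parent
            std::vector<Node *> lp_now;
            collect_leaf_parents(root, lp_now);
            int n_lp_new = (int)lp_now.size() + 1;
            if (leaf->parent && leaf->parent->l->is_leaf() &&
                leaf->parent->r->is_leaf())
              n_lp_new -= 1;
            double log_fwd = -std::log((double)growable.size()) -
                             std::log((double)vars.size()) -
                             std::log((double)ranges[var].count);
            double log_rev = -std::log((double)n_lp_new);
            double log_ratio = log_lik + log_prior + log_rev - log_fwd;
            if (std::log(unif_rand()) < log_ratio) {
              leaf->var = var; leaf->cut = cut;
              leaf->l = new Node(); leaf->r = new Node();
              leaf->l->parent = leaf; leaf->r->parent = leaf;
              leaf->l->depth = leaf->r->depth = leaf->depth + 1;
              structure_changed = true;
              ++accept;
            }
          }
        }
      } else if (u_move < 0.5) {
        // ---- PRUNE ----
        std::vector<Node *> lp;
        collect_leaf_parents(root, lp);
        if (!lp.empty()) {
          Node *nd = lp[sample_int((int)lp.size())];
          double cval = cp.cuts[nd->var][nd->cut];
          std::vector<int> here;
          for (int i = 0; i < n; ++i) {
            if (leaves[leaf_of[i]] == nd->l || leaves[leaf_of[i]] == nd->r)
              here.push_back(i);
          }
          double nl = 0, sl = 0, nr = 0, sr = 0;
          for (int t : here) {
            if (X(t, nd->var) <= cval) { nl += w[t]; sl += R[t]; }
            else { nr += w[t]; sr += R[t]; }
          }
          double ntot = nl + nr, stot = sl + sr;
          int d = nd->depth;
          double log_lik = leaf_lml(ntot, stot, s2mu) -
                           leaf_lml(nl, sl, s2mu) - leaf_lml(nr, sr, s2mu);
          double log_prior = log_pnosplit(d, alpha, beta) -
                             log_psplit(d, alpha, beta) -
                             2.0 * log_pnosplit(d + 1, alpha, beta);
          // reverse move grows the collapsed leaf with the same rule
          int growable_after = 0;
          for (int l = 0; l < L; ++l) {
            Node *lf = leaves[l];
            if (lf == nd->l || lf == nd->r) continue;
            if (!obs[l].empty()) ++growable_after;
          }
          if (!here.empty()) ++growable_after;  // the collapsed node itself
          std::vector<double> lo(p, R_PosInf), hi(p, R_NegInf);
          for (int t : here) {
            for (int jj = 0; jj < p; ++jj) {
              double xv = X(t, jj);
              if (xv < lo[jj]) lo[jj] = xv;
              if (xv > hi[jj]) hi[jj] = xv;
            }
          }
          int nvars = 0, ncuts_var = 0;
          for (int jj = 0; jj < p; ++jj) {
            CutRange r2 = valid_cuts(cp.cuts[jj], lo[jj], hi[jj]);
            if (r2.count > 0) ++nvars;
            if (jj == nd->var) ncuts_var = r2.count;
          }
          if (growable_after > 0 && nvars > 0 && ncuts_var > 0) {
            double log_fwd = -std::log((double)lp.size());
            double log_rev = -std::log((double)growable_after) -
                             std::log((double)nvars) -
                             std::log((double)ncuts_var);
            double log_ratio = log_lik + log_prior + log_rev - log_fwd;
            if (std::log(unif_rand()) < log_ratio) {
              delete nd->l; delete nd->r;
              nd->l = nd->r = nullptr;
              nd->var = -1; nd->cut = -1;
              structure_changed = true;
              ++accept;
            }
          }
        }
      } else {
        // ---- CHANGE (rule of a leaf-parent) ----
        std::vector<Node *> lp;
        collect_leaf_parents(root, lp);
        if (!lp.empty()) {
          Node *nd = lp[sample_int((int)lp.size())];
          std::vector<int> here;
          for (int i = 0; i < n; ++i) {
            if (leaves[leaf_of[i]] == nd->l || leaves[leaf_of[i]] == nd->r)
              here.push_back(i);
          }
          std::vector<double> lo(p, R_PosInf), hi(p, R_NegInf);
          for (int t : here) {
            for (int jj = 0; jj < p; ++jj) {
              double xv = X(t, jj);
              if (xv < lo[jj]) lo[jj] = xv;
              if (xv > hi[jj]) hi[jj] = xv;
            }
          }
          std::vector<int> vars;
          std::vector<CutRange> ranges(p);
          for (int jj = 0; jj < p; ++jj) {
            ranges[jj] = valid_cuts(cp.cuts[jj], lo[jj], hi[jj]);
            if (ranges[jj].count > 0) vars.push_back(jj);
          }
          if (!vars.empty()) {
            int var_new = vars[sample_int((int)vars.size())];
            int cut_new = ranges[var_new].first + sample_int(ranges[var_new].count);
            double cv_new = cp.cuts[var_new][cut_new];
            double cv_old = cp.cuts[nd->var][nd->cut];
            double nl_o = 0, sl_o = 0, nr_o = 0, sr_o = 0;
            double nl_n = 0, sl_n = 0, nr_n = 0, sr_n = 0;
            for (int t : here) {
              if (X(t, nd->var) <= cv_old) { nl_o += w[t]; sl_o += R[t]; }
              else { nr_o += w[t]; sr_o += R[t]; }
              if (X(t, var_new) <= cv_new) { nl_n += w[t]; sl_n += R[t]; }
              else { nr_n += w[t]; sr_n += R[t]; }
            }
            // proposal uniform over the same valid (var, cut) set both ways
            double log_lik = leaf_lml(nl_n, sl_n, s2mu) + leaf_lml(nr_n, sr_n, s2mu) -
                             leaf_lml(nl_o, sl_o, s2mu) - leaf_lml(nr_o, sr_o, s2mu);
            if (std::log(unif_rand()) < log_lik) {
              nd->var = var_new; nd->cut = cut_new;
              structure_changed = true;
              ++accept;
            }
          }
        }
      }

      if (structure_changed) {
        leaves.clear();
        collect_leaves(root, leaves);
        obs.assign(leaves.size(), std::vector<int>());
        for (int i = 0; i < n; ++i) {
          Node *nd = leaf_for(root, &X(i, 0), n, cp);
          leaf_of[i] = nd->idx;
          obs[nd->idx].push_back(i);
        }
      }

      // Gibbs draw of leaf values and fit update
      for (size_t l = 0; l < leaves.size(); ++l) {
        double nl = 0.0, Sl = 0.0;
        for (int t : obs[l]) { nl += w[t]; Sl += R[t]; }
        double post_var = s2mu / (1.0 + nl * s2mu);
        double post_mean = s2mu * Sl / (1.0 + nl * s2mu);
        leaves[l]->mu = post_mean + std::sqrt(post_var) * norm_rand();
      }
      for (int i = 0; i < n; ++i) {
        double newfit = leaves[leaf_of[i]]->mu;
        fhat[i] += newfit - fits[j][i];
        fits[j][i] = newfit;
      }
    }

    // latent sums refresh
    for (int i = 0; i < n; ++i) {
      double mi = offset + fhat[i];
      S[i] = rtnorm_sum(mi, successes[i], true) +
             rtnorm_sum(mi, trials[i] - successes[i], false);
    }

    if (iter >= nburn && ((iter - nburn) % thin == 0)) {
      for (int i = 0; i < n; ++i) train_draws(kept, i) = offset + fhat[i];
      for (int t = 0; t < m; ++t) {
        double f = offset;
        for (int j = 0; j < ntree; ++j)
          f += leaf_for(trees[j], &Xpred(t, 0), m, cp)->mu;
        pred_draws(kept, t) = f;
      }
      ++kept;
    }
    if (verbose && ((iter + 1) % 100 == 0))
      Rcpp::Rcout << "iter " << (iter + 1) << "/" << total_iter << "\n";
    Rcpp::checkUserInterrupt();
  }

  double depth_sum = 0;
  int leaf_count = 0;
  for (int j = 0; j < ntree; ++j) {
    std::vector<Node *> lv;
    collect_leaves(trees[j], lv);
    for (Node *nd : lv) depth_sum += nd->depth;
    leaf_count += (int)lv.size();
  }

  for (int j = 0; j < ntree; ++j) delete_tree(trees[j]);

  return List::create(
      _["pred"] = pred_draws,
      _["train"] = train_draws,
      _["accept_rate"] = proposals ? (double)accept / proposals : 0.0,
      _["mean_leaf_depth"] = depth_sum / std::max(1, leaf_count),
      _["offset"] = offset);
}
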