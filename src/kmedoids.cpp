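#include <Rcpp.h>
using namespace Rcpp;

// Total cost and nearest/second-nearest bookkeeping for PAM.
static double assign_cost(const NumericMatrix &d, const std::vector<int> &med,
                          std::vector<int> &n1, std::vector<double> &d1,
                          std::vector<double> &d2) {
  int n = d.nrow(), k = med.size();
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double b1 = R_PosInf, b2 = R_PosInf; int bi = -1;
    for (int j = 0; j < k; ++j) {
      double dist = d(i, med[j]);
      if (dist < b1) { b2 = b1; b1 = dist; bi = j; }
      else if (dist < b2) { b2 = dist; }
    }
    n1[i] = bi; d1[i] = b1; d2[i] = b2; total += b1;
  }
  return total;
}

// PAM: exact enumeration of all medoid sets when C(n,k) is small (the
// steepest-descent heuristic can stall in one-swap local optima), greedy
// BUILD then steepest-descent SWAP otherwise. Deterministic; cost ties are
// broken by the lowest candidate index / lexicographically first medoid
// set. The heuristic's cost is asserted non-increasing across iterations.
// [[Rcpp::export(name = ".pam_cpp")]]
List pam_cpp(NumericMatrix d, int k) {
  int n = d.nrow();
  if (d.ncol() != n) stop("distance matrix must be square");
  if (k < 2 || k > n - 1) stop("k must be in [2, n-1]");

  // number of candidate medoid sets, capped to detect the small regime
  double n_sets = 1.0;
  for (int i = 0; i < k; ++i) n_sets = n_sets * (n - i) / (i + 1);
  if (n_sets <= 2000.0) {
    std::vector<int> comb(k), best_med(k);
    for (int i = 0; i < k; ++i) comb[i] = i;
    double best_cost = R_PosInf;
    while (true) {
      double cost = 0.0;
      for (int i = 0; i < n; ++i) {
        double b = R_PosInf;
        for (int j = 0; j < k; ++j)
          if (d(i, comb[j]) < b) b = d(i, comb[j]);
        cost += b;
      }
      if (cost < best_cost - 1e-12) { best_cost = cost; best_med = comb; }
      int pos = k - 1;
      while (pos >= 0 && comb[pos] == n - k + pos) --pos;
      if (pos < 0) break;
      ++comb[pos];
      for (int j = pos + 1; j < k; ++j) comb[j] = comb[j - 1] + 1;
    }
    IntegerVector medoids(k), labels(n);
    for (int j = 0; j < k; ++j) medoids[j] = best_med[j] + 1;
    for (int i = 0; i < n; ++i) {
      double b = R_PosInf; int bi = 0;
      for (int j = 0; j < k; ++j)
        if (d(i, best_med[j]) < b) { b = d(i, best_med[j]); bi = j; }
      labels[i] = bi + 1;
    }
    return List::create(_["medoids"] = medoids, _["labels"] = labels,
                        _["cost"] = best_cost);
  }

  std::vector<int> med;
  std::vector<bool> is_med(n, false);

  // BUILD: first medoid minimizes total distance, then greedy additions
  {
    int best = 0; double bestc = R_PosInf;
    for (int i = 0; i < n; ++i) {
      double c = 0; for (int j = 0; j < n; ++j) c += d(j, i);
      if (c < bestc - 1e-12) { bestc = c; best = i; }
    }
    med.push_back(best); is_med[best] = true;
    std::vector<double> nearest(n);
    for (int i = 0; i < n; ++i) nearest[i] = d(i, best);
    while ((int)med.size() < k) {
      int bi = -1; double bgain = -1e-12;
      for (int c = 0; c < n; ++c) {
        if (is_med[c]) continue;
        double gain = 0;
        for (int i = 0; i < n; ++i) {
          double red = nearest[i] - d(i, c);
          if (red > 0) gain += red;
        }
        if (gain > bgain + 1e-12) { bgain = gain; bi = c; }
      }
      if (bi < 0) { // all remaining candidates tie at zero gain
        for (int c = 0; c < n; ++c) if (!is_med[c]) { bi = c; break; }
      }
      med.push_back(bi); is_med[bi] = true;
      for (int i = 0; i < n; ++i)
        if (d(i, bi) < nearest[i]) nearest[i] = d(i, bi);
    }
  }

  std::vector<int> n1(n); std::vector<double> d1(n), d2(n);
  double cost = assign_cost(d, med, n1, d1, d2);

  // SWAP: steepest descent over all (medoid, candidate) pairs
  for (int iter = 0; iter < 1000; ++iter) {
    double best_delta = -1e-9; int best_m = -1, best_h = -1;
    for (int h = 0; h < n; ++h) {
      if (is_med[h]) continue;
      for (int mj = 0; mj < k; ++mj) {
        double delta = 0;
        for (int i = 0; i < n; ++i) {
          double dih = d(i, h);
          double cur = d1[i];
          double nw = (n1[i] == mj) ? std::min(d2[i], dih) : std::min(cur, dih);
          delta += nw - cur;
        }
        if (delta < best_delta - 1e-12) {
          best_delta = delta; best_m = mj; best_h = h;
        }
      }
    }
    if (best_m < 0) break;
    is_med[med[best_m]] = false;
    med[best_m] = best_h; is_med[best_h] = true;
    double newcost = assign_cost(d, med, n1, d1, d2);
    if (newcost > cost + 1e-8) stop("internal error: PAM cost increased");
    cost = newcost;
  }

  IntegerVector medoids(k), labels(n);
  for (int j = 0; j < k; ++j) medoids[j] = med[j] + 1;
  for (int i = 0; i < n; ++i) labels[i] = n1[i] + 1;
  return List::create(_["medoids"] = medoids, _["labels"] = labels,
                      _["cost"] = cost);
}

// Lawson-Hanson active-set non-negative least squares: min ||A x - b||, x >= 0
// [[Rcpp::export(name = ".nnls_cpp")]]
NumericVector nnls_cpp(NumericMatrix A, NumericVector b) {
  int m = A.nrow(), p = A.ncol();
  if (b.size() != m) stop("dimension mismatch in NNLS");
  std::vector<bool> inP(p, false);
  NumericVector x(p);
  std::vector<double> w(p), resid(m);
  for (int i = 0; i < m; ++i) resid[i] = b[i];

  auto solve_ls = [&](const std::vector<int> &idx, std::vector<double> &z) {
    // normal equations with tiny ridge for safety on the active set
    int q = idx.size();
    std::vector<double> G(q * q), rhs(q);
    for (int a = 0; a < q; ++a) {
      for (int c = a; c < q; ++c) {
        double s = 0;
        for (int i = 0; i < m; ++i) s += A(i, idx[a]) * A(i, idx[c]);
        G[a * q + c] = G[c * q + a] = s;
      }
      G[a * q + a] += 1e-12;
      double s = 0;
      for (int i = 0; i < m; ++i) s += A(i, idx[a]) * b[i];
      rhs[a] = s;
    }
    // Cholesky solve
    for (int a = 0; a < q; ++a) {
      for (int c = 0; c < a; ++c) {
        double s = G[a * q + c];
        for (int t = 0; t < c; ++t) s -= G[a * q + t] * G[c * q + t];
        G[a * q + c] = s / G[c * q + c];
      }
      double s = G[a * q + a];
      for (int t = 0; t < a; ++t) s -= G[a * q + t] * G[a * q + t];
      if (s <= 0) s = 1e-12;
      G[a * q + a] = std::sqrt(s);
    }
    z.assign(q, 0.0);
    for (int a = 0; a < q; ++a) {
      double s = rhs[a];
      for (int t = 0; t < a; ++t) s -= G[a * q + t] * z[t];
      z[a] = s / G[a * q + a];
    }
    for (int a = q - 1; a >= 0; --a) {
      double s = z[a];
      for (int t = a + 1; t < q; ++t) s -= G[t * q + a] * z[t];
      z[a] = s / G[a * q + a];
    }
  };

  double w_ref = 0.0; // gradient scale from the first pass, for a relative
                      // stopping tolerance
  for (int outer = 0; outer < 30 * p; ++outer) {
    // w = A' (b - A x)
    for (int i = 0; i < m; ++i) {
      double s = 0;
      for (int j = 0; j < p; ++j) if (x[j] != 0) s += A(i, j) * x[j];
      resid[i] = b[i] - s;
    }
    int best = -1; double bw = 0.0;
    for (int j = 0; j < p; ++j) {
      if (inP[j]) continue;
      double s = 0;
      for (int i = 0; i < m; ++i) s += A(i, j) * resid[i];
      w[j] = s;
      if (s > bw) { bw = s; best = j; }
    }
    if (outer == 0) w_ref = (bw > 0) ? bw : 1.0;
    if (best < 0 || bw <= 1e-12 * w_ref) break;
    inP[best] = true;

    for (int inner = 0; inner < 30 * p; ++inner) {
      std::vector<int> idx;
      for (int j = 0; j < p; ++j) if (inP[j]) idx.push_back(j);
      std::vector<double> z;
      solve_ls(idx, z);
      bool finite = true;
      for (size_t a = 0; a < idx.size(); ++a)
        if (!std::isfinite(z[a])) { finite = false; break; }
      if (!finite) { // numerically degenerate set: back out the last entrant
        inP[best] = false;
        x[best] = 0.0;
        break;
      }
      bool feasible = true;
      for (size_t a = 0; a < idx.size(); ++a)
        if (z[a] <= 0) { feasible = false; break; }
      if (feasible) {
        for (int j = 0; j < p; ++j) x[j] = 0;
        for (size_t a = 0; a < idx.size(); ++a) x[idx[a]] = z[a];
        break;
      }
      double alpha = R_PosInf;
      for (size_t a = 0; a < idx.size(); ++a) {
        if (z[a] <= 0) {
          double denom = x[idx[a]] - z[a];
          double r = (denom > 0) ? x[idx[a]] / denom : 0.0;
          if (r < alpha) alpha = r;
        }
      }
      for (size_t a = 0; a < idx.size(); ++a) {
        double nx = x[idx[a]] + alpha * (z[a] - x[idx[a]]);
        x[idx[a]] = (nx < 1e-12) ? 0.0 : nx;
        if (x[idx[a]] == 0.0) inP[idx[a]] = false;
      }
    }
  }
  return x;
}
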