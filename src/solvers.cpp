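// Active-set solvers for the two constrained least-squares half-steps of the
// alternating factorization Y ~ W H:
//   H-step: per sample, min ||y - W h||^2  s.t.  h >= 0, sum(h) = 1
//   W-step: per feature, min ||y - H' w||^2 s.t.  0 <= w (<= upper)
// Both problems are strictly convex for full-rank designs; K (number of cell
// types) is small, so the per-column subproblems are tiny and an active-set
// strategy with exact KKT solves is fast and exact.

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve min 0.5 h'Qh - c'h  s.t. sum(h)=1, h>=0 for one column.
// Q must be positive definite (caller adds ridge if needed).
static vec simplex_qp(const mat& Q, const vec& c, int maxit = 200) {
  const uword K = Q.n_rows;
  if (K == 1) return vec(1, fill::ones);

  std::vector<bool> freev(K, true);
  uword nfree = K;
  vec h(K, fill::zeros);
  double lambda = 0.0;
  const double tol_h = 1e-12;
  const double tol_g = 1e-9 * (1.0 + norm(c, "inf"));

  for (int it = 0; it < maxit; ++it) {
    uvec F(nfree);
    uword j = 0;
    for (uword i = 0; i < K; ++i) if (freev[i]) F(j++) = i;

    // Solve the equality-constrained problem on the free set by eliminating
    // the sum-to-one constraint (pivot = last free variable).  The reduced
    // system keeps Q's scale throughout and avoids the badly scaled bordered
    // KKT matrix.
    vec hF(nfree);
    if (nfree == 1) {
      hF(0) = 1.0;
      lambda = c(F(0)) - Q(F(0), F(0));
    } else {
      const uword p = F(nfree - 1);
      mat M(nfree - 1, nfree - 1);
      vec rhs(nfree - 1);
      for (uword a = 0; a < nfree - 1; ++a) {
        const uword ia = F(a);
        for (uword b = 0; b < nfree - 1; ++b) {
          const uword ib = F(b);
          M(a, b) = Q(ia, ib) - Q(ia, p) - Q(p, ib) + Q(p, p);
        }
        rhs(a) = (c(ia) - c(p)) - (Q(ia, p) - Q(p, p));
      }
      vec z;
      if (!solve(z, M, rhs, solve_opts::no_approx)) {
        M.diag() += 1e-8 * (1.0 + trace(M) / std::max<uword>(1, nfree - 1));
        if (!solve(z, M, rhs, solve_opts::no_approx)) z = pinv(M) * rhs;
      }
      hF.head(nfree - 1) = z;
      hF(nfree - 1) = 1.0 - accu(z);
      vec hfull(K, fill::zeros);
      for (uword i = 0; i < nfree; ++i) hfull(F(i)) = hF(i);
      lambda = c(p) - dot(Q.row(p), hfull);
    }

    // clamp negative free variables (keep at least one free)
    uvec neg = find(hF < -tol_h);
    if (neg.n_elem > 0 && nfree > 1) {
      if (neg.n_elem >= nfree) {            // would empty the free set:
        uword keep = hF.index_max();        // keep the largest component
        for (uword i = 0; i < nfree; ++i)
          if (i != keep) freev[F(i)] = false;
        nfree = 1;
      } else {
        for (uword i = 0; i < neg.n_elem; ++i) freev[F(neg(i))] = false;
        nfree -= neg.n_elem;
      }
      continue;
    }

    h.zeros();
    for (uword i = 0; i < nfree; ++i) h(F(i)) = std::max(hF(i), 0.0);

    // KKT multiplier check for clamped variables: mu_i = (Qh - c)_i + lambda >= 0
    if (nfree == K) return h;
    vec g = Q * h - c;
    double worst = -tol_g;
    int worst_i = -1;
    for (uword i = 0; i < K; ++i) {
      if (freev[i]) continue;
      double mu = g(i) + lambda;
      if (mu < worst) { worst = mu; worst_i = (int)i; }
    }
    if (worst_i < 0) return h;
    freev[(uword)worst_i] = true;
    ++nfree;
  }
  return h;  // iteration cap: return current feasible iterate
}

// Solve min 0.5 w'Qw - c'w  s.t. lower=0 <= w <= upper (upper may be +Inf).
static vec box_qp(const mat& Q, const vec& c, double upper, int maxit = 200) {
  const uword K = Q.n_rows;
  // status: 0 free, -1 at lower bound, +1 at upper bound
  std::vector<int> st(K, 0);
  vec w(K, fill::zeros);
  const bool has_up = std::isfinite(upper);
  const double tol_g = 1e-9 * (1.0 + norm(c, "inf"));

  for (int it = 0; it < maxit; ++it) {
    uvec F = uvec();
    {
      std::vector<uword> f;
      for (uword i = 0; i < K; ++i) if (st[i] == 0) f.push_back(i);
      F = conv_to<uvec>::from(f);
    }
    w.zeros();
    for (uword i = 0; i < K; ++i) if (st[i] == 1) w(i) = upper;

    bool clamped = false;
    if (F.n_elem > 0) {
      vec rhs = c.elem(F);
      if (has_up) {
        for (uword i = 0; i < K; ++i)
          if (st[i] == 1) rhs -= Q.submat(F, uvec{ i }) * upper;
      }
      mat QFF = Q.submat(F, F);
      vec wF;
      if (!solve(wF, QFF, rhs, solve_opts::no_approx)) {
        QFF.diag() += 1e-8 * (1.0 + trace(Q) / K);
        if (!solve(wF, QFF, rhs, solve_opts::no_approx))
          wF = pinv(QFF) * rhs;             // last resort, warning-free
      }
      for (uword i = 0; i < F.n_elem; ++i) {
        if (wF(i) < 0.0) { st[F(i)] = -1; clamped = true; }
        else if (has_up && wF(i) > upper) { st[F(i)] = 1; clamped = true; }
        else w(F(i)) = wF(i);
      }
    }
    if (clamped) continue;

    // multiplier check: at lower need g >= 0, at upper need g <= 0
    vec g = Q * w - c;
    double worst = tol_g;
    int worst_i = -1;
    for (uword i = 0; i < K; ++i) {
      if (st[i] == 0) continue;
      double viol = (st[i] == -1) ? -g(i) : g(i);
      if (viol > worst) { worst = viol; worst_i = (int)i; }
    }
    if (worst_i < 0) return w;
    st[(uword)worst_i] = 0;
  }
  return w;
}

static void add_ridge_if_needed(mat& Q) {
  double rc = rcond(Q);
  if (!std::isfinite(rc) || rc < 1e-10)
    Q.diag() += 1e-8 * (1.0 + trace(Q) / Q.n_rows);
}

// Batch simplex-constrained solve: columns sharing an active-set pattern are
// solved together with one KKT factorization.  Per-column active-set logic
// (clamp violating entries, release the worst KKT multiplier) is applied
// synchronously; unresolved columns fall back to the per-column solver.
static mat simplex_ls_batch(const mat& Q, const mat& C) {
  const uword K = Q.n_rows, N = C.n_cols;
  mat H(K, N, fill::zeros);
  if (K == 1) { H.ones(); return H; }
  std::vector<uint32_t> pat(N, 0);        // bit k set = clamped to zero
  std::vector<bool> done(N, false);
  vec lambda(N, fill::zeros);
  const double tol_h = 1e-12;

  for (int it = 0; it < 100; ++it) {
    std::unordered_map<uint32_t, std::vector<uword>> groups;
    for (uword s = 0; s < N; ++s)
      if (!done[s]) groups[pat[s]].push_back(s);
    if (groups.empty()) break;

    for (auto& kv : groups) {
      const uint32_t key = kv.first;
      const std::vector<uword>& cols = kv.second;
      std::vector<uword> fr;
      for (uword i = 0; i < K; ++i)
        if (!(key & (1u << i))) fr.push_back(i);
      const uword nf = fr.size();
      uvec F = conv_to<uvec>::from(fr);
      uvec G = conv_to<uvec>::from(cols);
      if (nf == 1) {
        for (uword j = 0; j < cols.size(); ++j) {
          const uword s = cols[j];
          H.col(s).zeros();
          H(F(0), s) = 1.0;
          lambda(s) = C(F(0), s) - Q(F(0), F(0));
        }
        continue;
      }
      // reduced system: eliminate the sum-to-one constraint (pivot = last
      // free variable) so the solve stays on Q's scale
      const uword p = F(nf - 1);
      mat M(nf - 1, nf - 1);
      vec adj(nf - 1);
      for (uword a = 0; a < nf - 1; ++a) {
        const uword ia = F(a);
        for (uword b = 0; b < nf - 1; ++b) {
          const uword ib = F(b);
          M(a, b) = Q(ia, ib) - Q(ia, p) - Q(p, ib) + Q(p, p);
        }
        adj(a) = Q(ia, p) - Q(p, p);
      }
      mat B(nf - 1, cols.size());
      for (uword j = 0; j < cols.size(); ++j) {
        const uword s = cols[j];
        for (uword a = 0; a < nf - 1; ++a)
          B(a, j) = (C(F(a), s) - C(p, s)) - adj(a);
      }
      mat S;
      if (!solve(S, M, B, solve_opts::no_approx)) {
        M.diag() += 1e-8 * (1.0 + trace(M) / std::max<uword>(1, nf - 1));
        if (!solve(S, M, B, solve_opts::no_approx)) S = pinv(M) * B;
      }
      for (uword j = 0; j < cols.size(); ++j) {
        const uword s = cols[j];
        H.col(s).zeros();
        double tot = 0.0;
        for (uword i = 0; i < nf - 1; ++i) { H(F(i), s) = S(i, j); tot += S(i, j); }
        H(p, s) = 1.0 - tot;
        lambda(s) = C(p, s) - dot(Q.row(p), H.col(s));
      }
    }

    // clamp negatives / release worst multiplier, per column
    mat Gr = Q * H - C;                    // gradient part, all columns
    bool any_active = false;
    for (uword s = 0; s < N; ++s) {
      if (done[s]) continue;
      uint32_t key = pat[s];
      uword nf = 0;
      double hmax = -datum::inf; uword imax = 0;
      bool viol = false;
      for (uword i = 0; i < K; ++i) {
        if (key & (1u << i)) continue;
        ++nf;
        if (H(i, s) > hmax) { hmax = H(i, s); imax = i; }
        if (H(i, s) < -tol_h) viol = true;
      }
      if (viol) {
        uint32_t nk = key;
        uword left = nf;
        for (uword i = 0; i < K; ++i) {
          if (key & (1u << i)) continue;
          if (H(i, s) < -tol_h && left > 1) { nk |= (1u << i); --left; }
        }
        pat[s] = nk;
        any_active = true;
        continue;
      }
      // feasible: zero out tiny negatives, check multipliers of clamped set
      for (uword i = 0; i < K; ++i)
        if (!(key & (1u << i)) && H(i, s) < 0) H(i, s) = 0;
      const double tol_g = 1e-9 * (1.0 + arma::abs(C.col(s)).max());
      double worst = -tol_g; int worst_i = -1;
      for (uword i = 0; i < K; ++i) {
        if (!(key & (1u << i))) continue;
        double mu = Gr(i, s) + lambda(s);
        if (mu < worst) { worst = mu; worst_i = (int)i; }
      }
      if (worst_i < 0) { done[s] = true; }
      else { pat[s] = key & ~(1u << (uword)worst_i); any_active = true; }
    }
    if (!any_active) break;
  }
  for (uword s = 0; s < N; ++s)
    if (!done[s]) H.col(s) = simplex_qp(Q, C.col(s));
  return H;
}

// Batch box-constrained solve with the same pattern-grouping strategy.
// Pattern encoding: 2 bits per variable (0 free, 1 at lower, 2 at upper).
static mat box_ls_batch(const mat& Q, const mat& C, double upper) {
  const uword K = Q.n_rows, M = C.n_cols;
  mat Wt(K, M, fill::zeros);
  const bool has_up = std::isfinite(upper);
  std::vector<uint32_t> pat(M, 0);
  std::vector<bool> done(M, false);

  for (int it = 0; it < 100; ++it) {
    std::unordered_map<uint32_t, std::vector<uword>> groups;
    for (uword p = 0; p < M; ++p)
      if (!done[p]) groups[pat[p]].push_back(p);
    if (groups.empty()) break;

    for (auto& kv : groups) {
      const uint32_t key = kv.first;
      const std::vector<uword>& cols = kv.second;
      std::vector<uword> fr, up;
      for (uword i = 0; i < K; ++i) {
        uint32_t st = (key >> (2 * i)) & 3u;
        if (st == 0) fr.push_back(i);
        else if (st == 2) up.push_back(i);
      }
      uvec G = conv_to<uvec>::from(cols);
      if (fr.empty()) {
        for (uword j = 0; j < cols.size(); ++j) {
          Wt.col(cols[j]).zeros();
          for (uword u : up) Wt(u, cols[j]) = upper;
        }
        continue;
      }
      uvec F = conv_to<uvec>::from(fr);
      mat B = C.submat(F, G);
      if (!up.empty()) {
        vec adj(F.n_elem, fill::zeros);
        for (uword u : up) adj += Q.submat(F, uvec{ u }) * upper;
        B.each_col() -= adj;
      }
      mat QFF = Q.submat(F, F);
      mat S;
      if (!solve(S, QFF, B, solve_opts::no_approx)) {
        QFF.diag() += 1e-8 * (1.0 + trace(Q) / K);
        if (!solve(S, QFF, B, solve_opts::no_approx)) S = pinv(QFF) * B;
      }
      for (uword j = 0; j < cols.size(); ++j) {
        const uword p = cols[j];
        Wt.col(p).zeros();
        for (uword u : up) Wt(u, p) = upper;
        for (uword i = 0; i < F.n_elem; ++i) Wt(F(i), p) = S(i, j);
      }
    }

    mat Gr = Q * Wt - C;
    bool any_active = false;
    for (uword p = 0; p < M; ++p) {
      if (done[p]) continue;
      uint32_t key = pat[p], nk = key;
      bool viol = false;
      for (uword i = 0; i < K; ++i) {
        if (((key >> (2 * i)) & 3u) != 0) continue;
        if (Wt(i, p) < 0.0) { nk |= (1u << (2 * i)); viol = true; }
        else if (has_up && Wt(i, p) > upper) { nk |= (2u << (2 * i)); viol = true; }
      }
      if (viol) {
        pat[p] = nk;
        // project onto bounds so intermediate iterates stay sane
        for (uword i = 0; i < K; ++i) {
          if (Wt(i, p) < 0.0) Wt(i, p) = 0.0;
          else if (has_up && Wt(i, p) > upper) Wt(i, p) = upper;
        }
        any_active = true;
        continue;
      }
      const double tol_g = 1e-9 * (1.0 + arma::abs(C.col(p)).max());
      double worst = tol_g; int worst_i = -1;
      for (uword i = 0; i < K; ++i) {
        uint32_t st = (key >> (2 * i)) & 3u;
        if (st == 0) continue;
        double v = (st == 1) ? -Gr(i, p) : Gr(i, p);
        if (v > worst) { worst = v; worst_i = (int)i; }
      }
      if (worst_i < 0) { done[p] = true; }
      else { pat[p] = key & ~(3u << (2 * (uword)worst_i)); any_active = true; }
    }
    if (!any_active) break;
  }
  for (uword p = 0; p < M; ++p)
    if (!done[p]) Wt.col(p) = box_qp(Q, C.col(p), upper);
  return Wt;
}

// H-step over all samples: W is M x K, Y is M x N; returns K x N.
// [[Rcpp::export]]
arma::mat cpp_simplex_ls(const arma::mat& W, const arma::mat& Y) {
  mat Q = W.t() * W;
  add_ridge_if_needed(Q);
  mat C = W.t() * Y;
  if (W.n_cols > 12)  {                   // pattern keys need K <= 12
    mat H(W.n_cols, Y.n_cols);
    for (uword s = 0; s < Y.n_cols; ++s)
      H.col(s) = simplex_qp(Q, C.col(s));
    return H;
  }
  return simplex_ls_batch(Q, C);
}

// W-step over all features: H is K x N, Y is M x N; returns M x K.
// [[Rcpp::export]]
arma::mat cpp_box_ls(const arma::mat& H, const arma::mat& Y, double upper) {
  mat Q = H * H.t();
  add_ridge_if_needed(Q);
  mat C = H * Y.t();         // K x M
  if (H.n_rows > 12) {
    mat W(Y.n_rows, H.n_rows);
    for (uword p = 0; p < Y.n_rows; ++p)
      W.row(p) = box_qp(Q, C.col(p), upper).t();
    return W;
  }
  return box_ls_batch(Q, C, upper).t();
}

// Full alternating constrained least-squares loop.  Returns W, H, the
// Frobenius objective after every full iteration, and a convergence flag.
// [[Rcpp::export]]
Rcpp::List cpp_als(const arma::mat& Y, arma::mat W, arma::mat H,
                   double upper, double tol, int max_inner) {
  std::vector<double> obj;
  obj.reserve(64);
  double f_prev = datum::inf;
  bool converged = false;
  int t = 0;
  for (; t < max_inner; ++t) {
    H = cpp_simplex_ls(W, Y);
    W = cpp_box_ls(H, Y, upper);
    double f = accu(square(Y - W * H));
    obj.push_back(f);
    if (std::isfinite(f_prev) &&
        (f_prev - f) <= tol * std::max(f_prev, 1e-300)) {
      converged = true;
      ++t;
      break;
    }
    f_prev = f;
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("n_inner") = (int)obj.size());
}
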