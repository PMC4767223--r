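#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear soft-margin C-SVC solved in the dual by SMO with maximal-violating-pair
// working-set selection, operating on a precomputed Gram matrix. Training
// samples are addressed through global indices into K so that cross-validation
// folds and subsampled training sets reuse one Gram computation.
//
// KKT bookkeeping: with f_t = sum_s alpha_s y_s K(s,t), the quantity
// (y_t - f_t) is a lower bound on the bias b for t in I_up and an upper bound
// for t in I_low; optimality holds when max_{I_up}(y-f) <= min_{I_low}(y-f)
// + tol, and b = (max + min)/2.
static int smo_gram(const double* K, int N, const int* gidx, int ntr,
                    const int* y, double C, double tol, int max_iter,
                    std::vector<double>& alpha, double& b)
{
    const double eps_a = 1e-12;
    alpha.assign(ntr, 0.0);
    std::vector<double> f(ntr, 0.0);

    int iter = 0;
    double up_val = 0.0, low_val = 0.0;
    for (iter = 0; iter < max_iter; ++iter) {
        // first index: maximal violator in I_up
        int i_up = -1;
        up_val = -HUGE_VAL;
        low_val = HUGE_VAL;
        for (int t = 0; t < ntr; ++t) {
            const double v = y[t] - f[t];
            const bool in_up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0.0);
            const bool in_low = (y[t] > 0) ? (alpha[t] > 0.0) : (alpha[t] < C);
            if (in_up && v > up_val) { up_val = v; i_up = t; }
            if (in_low && v < low_val) low_val = v;
        }
        if (i_up < 0 || up_val - low_val < tol) break;

        // second index: largest decrease of the dual objective among the
        // indices in I_low that violate optimality with i (second-order
        // working-set selection)
        const int i = i_up;
        const int gi = gidx[i];
        const double Kii = K[gi + (size_t)N * gi];
        const double* Ki_col = K + (size_t)N * gi;
        int i_low = -1;
        double best = HUGE_VAL;
        for (int t = 0; t < ntr; ++t) {
            const bool in_low = (y[t] > 0) ? (alpha[t] > 0.0) : (alpha[t] < C);
            if (!in_low) continue;
            const double bt = up_val - (y[t] - f[t]);
            if (bt <= 0.0) continue;
            const int gt = gidx[t];
            double at = Kii + K[gt + (size_t)N * gt] - 2.0 * Ki_col[gt];
            if (at <= 1e-12) at = 1e-12;
            const double gain = -(bt * bt) / at;
            if (gain < best) { best = gain; i_low = t; }
        }
        if (i_low < 0) break;

        const int j = i_low;
        const int gj = gidx[j];
        const double Kjj = K[gj + (size_t)N * gj];
        const double Kij = Ki_col[gj];

        const double ai = alpha[i], aj = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
            L = std::max(0.0, aj - ai);
            H = std::min(C, C + aj - ai);
        } else {
            L = std::max(0.0, ai + aj - C);
            H = std::min(C, ai + aj);
        }

        const double Ei = f[i] - y[i], Ej = f[j] - y[j];
        const double eta = Kii + Kjj - 2.0 * Kij;
        double aj_new;
        if (eta > 1e-12) {
            aj_new = aj + y[j] * (Ei - Ej) / eta;
            if (aj_new < L) aj_new = L; else if (aj_new > H) aj_new = H;
        } else {
            // flat direction: move to whichever bound decreases the objective
            aj_new = (y[j] * (Ei - Ej) > 0.0) ? H : L;
        }
        double ai_new = ai + (double)(y[i] * y[j]) * (aj - aj_new);
        // snap to the box so rounding error never pins a variable just
        // inside a bound (which would stall the violating-pair selection)
        if (aj_new < eps_a) aj_new = 0.0; else if (aj_new > C - eps_a) aj_new = C;
        if (ai_new < eps_a) ai_new = 0.0; else if (ai_new > C - eps_a) ai_new = C;
        if (std::fabs(aj_new - aj) < 1e-14 && std::fabs(ai_new - ai) < 1e-14)
            break;

        const double di = (ai_new - ai) * y[i];
        const double dj = (aj_new - aj) * y[j];
        alpha[i] = ai_new;
        alpha[j] = aj_new;
        const double* Ki = K + (size_t)N * gi;  // column gi (K symmetric)
        const double* Kj = K + (size_t)N * gj;
        for (int t = 0; t < ntr; ++t) {
            const int gt = gidx[t];
            f[t] += di * Ki[gt] + dj * Kj[gt];
        }
    }
    b = 0.5 * (up_val + low_val);
    return iter;
}

// [[Rcpp::export]]
List svc_train_cpp(NumericMatrix Xt, IntegerVector y, double c_param,
                   double tol, int max_iter)
{
    const int d = Xt.nrow(), n = Xt.ncol();
    if (y.size() != n) stop("label length does not match the number of samples");
    const double* X = REAL(Xt);

    std::vector<double> K((size_t)n * n);
    for (int i = 0; i < n; ++i) {
        const double* xi = X + (size_t)i * d;
        for (int j = 0; j <= i; ++j) {
            const double* xj = X + (size_t)j * d;
            double s = 0.0;
            for (int k = 0; k < d; ++k) s += xi[k] * xj[k];
            K[i + (size_t)n * j] = s;
            K[j + (size_t)n * i] = s;
        }
    }
    std::vector<int> gidx(n);
    for (int i = 0; i < n; ++i) gidx[i] = i;

    std::vector<double> alpha;
    double b = 0.0;
    int iter = smo_gram(K.data(), n, gidx.data(), n, INTEGER(y), c_param,
                        tol, max_iter, alpha, b);

    NumericVector w(d);
    for (int i = 0; i < n; ++i) {
        if (alpha[i] == 0.0) continue;
        const double coef = alpha[i] * y[i];
        const double* xi = X + (size_t)i * d;
        for (int k = 0; k < d; ++k) w[k] += coef * xi[k];
    }
    return List::create(_["w"] = w, _["b"] = b,
                        _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                        _["iterations"] = iter);
}

// One leave-one-run-out fold: train on every run but r (optionally balancing
// the training classes by a run-stratified subsample drawn from R's RNG
// stream), test on run r. Returns the fold accuracy.
static double fold_accuracy(const double* Kp, int n, const int* y01,
                            const int* run, int r, bool balance,
                            double c_param, double tol, int max_iter,
                            std::vector<int>& idx0, std::vector<int>& idx1,
                            std::vector<int>& keep, std::vector<int>& ytr,
                            std::vector<double>& alpha)
{
    idx0.clear(); idx1.clear();
    for (int i = 0; i < n; ++i) {
        if (run[i] == r) continue;
        if (y01[i] == 0) idx0.push_back(i); else idx1.push_back(i);
    }
    if (idx0.empty() || idx1.empty())
        stop("a training fold lost one of the classes");

    keep.clear();
    if (balance && idx0.size() != idx1.size()) {
        // Run-stratified subsample: within each training run, draw from the
        // run's majority class as many items as its minority class has, so
        // every run contributes equally after balancing. An unstratified
        // draw leaves the subsampled class with uneven run representation,
        // which measurably biases the classifier toward predicting it less
        // often (null accuracy drifts ~0.3 points above chance on pooled
        // contrasts); stratification removes that bias.
        int max_run = 0;
        for (int i = 0; i < n; ++i) if (run[i] > max_run) max_run = run[i];
        for (int g = 0; g <= max_run; ++g) {
            if (g == r) continue;
            std::vector<int> g0, g1;
            for (int i = 0; i < n; ++i) {
                if (run[i] != g) continue;
                if (y01[i] == 0) g0.push_back(i); else g1.push_back(i);
            }
            std::vector<int>& maj = (g0.size() > g1.size()) ? g0 : g1;
            std::vector<int>& mnr = (g0.size() > g1.size()) ? g1 : g0;
            const int m = (int)mnr.size();
            // partial Fisher-Yates draw of m items from the run's majority
            for (int k = 0; k < m; ++k) {
                int pick = k + (int)std::floor(unif_rand() * (maj.size() - k));
                if (pick >= (int)maj.size()) pick = (int)maj.size() - 1;
                std::swap(maj[k], maj[pick]);
            }
            keep.insert(keep.end(), mnr.begin(), mnr.end());
            keep.insert(keep.end(), maj.begin(), maj.begin() + m);
        }
    } else {
        keep.assign(idx0.begin(), idx0.end());
        keep.insert(keep.end(), idx1.begin(), idx1.end());
    }

    const int ntr = (int)keep.size();
    ytr.resize(ntr);
    for (int t = 0; t < ntr; ++t) ytr[t] = (y01[keep[t]] == 1) ? 1 : -1;

    double b = 0.0;
    smo_gram(Kp, n, keep.data(), ntr, ytr.data(), c_param, tol, max_iter,
             alpha, b);

    int n_test = 0, n_correct = 0;
    for (int i = 0; i < n; ++i) {
        if (run[i] != r) continue;
        double s = b;
        const double* Kcol = Kp + (size_t)n * i;
        for (int t = 0; t < ntr; ++t) {
            if (alpha[t] == 0.0) continue;
            s += alpha[t] * ytr[t] * Kcol[keep[t]];
        }
        const int pred = (s > 0.0) ? 1 : 0;
        ++n_test;
        if (pred == y01[i]) ++n_correct;
    }
    return (n_test > 0) ? (double)n_correct / n_test : NA_REAL;
}

// Leave-one-run-out accuracies for one labelling, given the full Gram matrix
// K (n x n) of all patterns. run holds 0-based fold codes 0..(n_folds-1);
// y01 holds 0/1 class codes. When balance is true and the training classes
// are unequal, the majority class is subsampled to the minority size using
// R's RNG stream (reproducible under set.seed). Test folds are never
// subsampled.
// [[Rcpp::export]]
NumericVector loro_accuracy_cpp(NumericMatrix K, IntegerVector y01,
                                IntegerVector run, bool balance,
                                double c_param, double tol, int max_iter)
{
    const int n = K.nrow();
    if (K.ncol() != n) stop("K must be square");
    if (y01.size() != n || run.size() != n)
        stop("labels/run ids do not match the number of samples");
    int n_folds = 0;
    for (int i = 0; i < n; ++i) if (run[i] + 1 > n_folds) n_folds = run[i] + 1;

    const double* Kp = REAL(K);
    NumericVector acc(n_folds);
    std::vector<int> idx0, idx1, keep, ytr;
    std::vector<double> alpha;
    for (int r = 0; r < n_folds; ++r)
        acc[r] = fold_accuracy(Kp, n, INTEGER(y01), INTEGER(run), r, balance,
                               c_param, tol, max_iter, idx0, idx1, keep, ytr,
                               alpha);
    return acc;
}

// Null-permutation leave-one-run-out accuracies: the condition labels are
// shuffled within each run independently for every test fold ("per test"),
// so fold outcomes are mutually independent. Uses R's RNG stream for both
// the shuffles and any balancing subsamples (reproducible under set.seed).
// [[Rcpp::export]]
NumericVector loro_null_accuracy_cpp(NumericMatrix K, IntegerVector y01,
                                     IntegerVector run, bool balance,
                                     double c_param, double tol, int max_iter)
{
    const int n = K.nrow();
    if (K.ncol() != n) stop("K must be square");
    if (y01.size() != n || run.size() != n)
        stop("labels/run ids do not match the number of samples");
    int n_folds = 0;
    for (int i = 0; i < n; ++i) if (run[i] + 1 > n_folds) n_folds = run[i] + 1;

    // index lists per run group (runs double as folds)
    std::vector< std::vector<int> > groups(n_folds);
    for (int i = 0; i < n; ++i) groups[run[i]].push_back(i);

    const double* Kp = REAL(K);
    const int* y0 = INTEGER(y01);
    NumericVector acc(n_folds);
    std::vector<int> yperm(n), idx0, idx1, keep, ytr;
    std::vector<double> alpha;

    for (int r = 0; r < n_folds; ++r) {
        for (int i = 0; i < n; ++i) yperm[i] = y0[i];
        for (int g = 0; g < n_folds; ++g) {
            std::vector<int>& grp = groups[g];
            // Fisher-Yates shuffle of the labels within this run
            for (int k = (int)grp.size() - 1; k > 0; --k) {
                int pick = (int)std::floor(unif_rand() * (k + 1));
                if (pick > k) pick = k;
                std::swap(yperm[grp[k]], yperm[grp[pick]]);
            }
        }
        acc[r] = fold_accuracy(Kp, n, yperm.data(), INTEGER(run), r, balance,
                               c_param, tol, max_iter, idx0, idx1, keep, ytr,
                               alpha);
    }
    return acc;
}
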