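# Default stopword list (one term per line, '#' comments ignored).
# The published study's own list is not available; this list covers common
# Chinese function words plus English function words, and is meant to be
# edited per corpus.
的
了
和
与
及
或
在
是
对
为
于
由
以
将
按
把
该
其
等
并
而
这
那
各
每
本
所
有关
关于
根据
以及
应当
可以
进行
通过
如下
the
a
an
and
or
of
to
in
on
for
by
with
is
are
be
as
at
that
this
it
from
shall
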