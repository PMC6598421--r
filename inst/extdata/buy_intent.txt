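how much
what is the price
whats the price
price for
price list
do you ship
can you ship
can i order
how do i order
i want to buy
i want some
id like to buy
interested in buying
dm me the price
send me the menu
hook me up
how many for
is it available
still available
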